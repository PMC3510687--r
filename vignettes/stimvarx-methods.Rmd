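---
title: "Modeling stimulation-evoked intracerebral activity with stimvarx"
author: "stimvarx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stimulation-evoked intracerebral activity with stimvarx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimvarx)
```

## The modeling problem

Direct electrical stimulation of the cortex during presurgical epilepsy
monitoring evokes responses at distant recording sites (SEEG depth
electrodes). The response has two parts: a *deterministic* component driven
by the stimulus, and ongoing *spontaneous* activity. A plain vector
autoregression (MVAR) fit to such data is misspecified — the time-varying
evoked mean masquerades as spurious coupling. stimvarx instead fits a
stationary MVAR model **with an exogenous input** (MVARX):

$$y_n = \sum_{i=1}^{p} A_i\, y_{n-i} \;+\; \sum_{i=0}^{\ell} b_i\, x_{n-i}
\;+\; w_n,$$

where $y_n \in \mathbb{R}^d$ is the recording, $x_n$ the scalar stimulus
trigger, $w_n \sim \mathcal N(0, Q)$ i.i.d. innovations. The lag matrices
$A_1,\dots,A_p$ carry the inter-site coupling (entry $(m,n)$ of $A_i$ is the
influence of channel $n$ on channel $m$ at lag $i$); row $i$ of
$B = [b_0 \dots b_\ell]$ is an FIR filter describing direct propagation of
the stimulus to channel $i$ (fibers of passage). Because the evoked mean is
modeled explicitly, nothing is subtracted from the data and no SNR is lost.

The recording decomposes as $y_n = y_{n,e} + y_{n,s}$, where the *evoked*
component $y_{n,e}$ is the model driven by the stimulus train from zero
initial conditions (state carried across pulses, so late responses to one
pulse bleed into the next epoch), and the *spontaneous* component $y_{n,s}$
is the innovation-driven remainder. `simulate_session()` constructs
synthetic data exactly this way — evoked recursion plus a stationary
noise-only run — so the decomposition identity is bit-exact by
construction, and `mvarx_decompose()` recovers it.

## Pipeline and parameters

`run_pipeline()` chains the stages; each is exposed separately.

**Artifact removal** (`tukey_median_clean`). Volume-conduction artifacts
within ~39 ms of each pulse are removed by blending the raw signal with an
order-19 running median under a Tukey (cosine-tapered) weight: weight 1 for
|t| ≤ 10 ms around the pulse, cosine taper over 10–19 ms, zero at |t| ≥
20 ms. Samples outside the window are bit-identical to the input — the
tests assert this. The one-sample ambiguity in where the taper reaches zero
is fixed as: taper support [10, 19] ms, w = 0 at |t| ≥ 20 ms. Median-filter
edges use the running-median's standard endrule; stimuli never sit that
close to the recording edge in practice.

**Anti-alias downsampling** (`antialias_downsample`). A linear-phase FIR
lowpass with 48 Hz passband edge and 49.9 Hz stopband edge (suppressing
50 Hz mains and everything above the post-decimation Nyquist) is applied
with group-delay compensation, then the signal is decimated by 10 to
100 Hz. No FIR design routine ships with the pre-installed R stack, so the
filter is a Kaiser-window design (~1177 taps for ≥ 40 dB at a 1.9 Hz
transition); the tests verify the realized frequency response (unity DC
gain, ≥ 40 dB at 49.9 and 50 Hz, zero net delay) rather than trusting the
design formula. The trigger channel passes through the *same* filter chain,
so the model's input is the smoothed pulse the data actually saw; its scale
is absorbed into $B$. `binary_trigger = TRUE` bypasses this for purely
synthetic work.

**Epoching** (`segment_epochs`). Fixed 100-sample epochs at 100 Hz, from 12
samples before each pulse to 87 after (stimulus at within-epoch index 13,
1-based). Indices are 1-based with closed windows throughout, the R
convention.

**Outlier rejection** (`reject_outliers`). Epoch $m$ is scored by the
leave-one-out squared Mahalanobis distance $D^2(m)$ against the
time-varying ensemble mean and covariance of the other epochs, and removed
when $D^2(m) > Nd + 60\sqrt{2Nd}$ — the chi-squared mean plus 60 SDs, a
deliberately permissive rule that only catches gross deviations such as
sleep slow waves (emulated by `inject_outliers()` as an epoch-length
half-sine). Two numerical notes. First, with ~29 epochs and up to 12
channels the per-sample covariance can be ill-conditioned; diagonal loading
$10^{-6}\,(\mathrm{tr}\,\Sigma/d)\,I$ is applied when the condition number
exceeds $10^{10}$, and reported. Second, the chi-squared story is an
approximation: with *estimated* moments the exact mean of $D^2$ is
$Nd \cdot \frac{J-2}{J-2-d-1}\cdot\frac{J}{J-1}$ (≈ 504 rather than 400 at
$J=30, d=4$) — the unit tests assert this exact value; the 60-SD threshold
is far enough out that the distinction never changes a decision. After
rejection, model fitting uses the *maximum contiguous segments* of
surviving epochs (`merge_retained_epochs`), which minimizes samples lost to
initial conditions.

**Estimation** (`mvarx_fit`). With $z_{n-1} = [y_{n-1}^T \dots y_{n-p}^T,
x_n, \dots, x_{n-\ell}]^T$ and $n_0 = \max(p,\ell)$ initial samples per
segment, $\hat\Theta = (\sum_j Y_j Z_j^T)(\sum_j Z_j Z_j^T)^{-1}$ and
$\hat Q$ is the residual covariance over $N_t = \sum_j N_j - n_0 J$ —
the maximum-likelihood estimate under Gaussian innovations. The solve uses
a QR factorization of the stacked regressors rather than the normal
equations; rank deficiency raises an actionable error. $\ell = 10$
(100 ms at 100 Hz) by default, matching the physiological duration of
direct stimulus propagation; capping $\ell$ also prevents $B$ from
swallowing the long-range coupling that belongs in $A$.

**Order selection** (`select_order`). $p$ is chosen by cross-validation
over a default grid 1..30. Test sets are *contiguous* blocks of epochs
(deterministic, no seed) so each spans a similar stretch of time under
slow state drift; default $M \approx J/3$ partitions of ~3 epochs. Two
errors are combined: the one-step prediction error CV$_e$ and the
average-response error CV$_\epsilon$, whose model average is computed by
driving the *entire* stimulus train through the model so cross-epoch
carry-over is reproduced. Both error surfaces are normalized by their
overall medians (two-pass) and averaged; ties go to the smaller $p$.
A caution from the synthetic experiments: when the generator's AR content
decays geometrically across lags, CV legitimately prefers smaller orders —
order recovery is only a sharp test when the true high-lag dynamics are
strong.

**Whiteness diagnostics** (`whiteness_test`). Consistency of OLS requires
serially uncorrelated residuals. The package implements the kernel-weighted
portmanteau statistic over lagged residual covariances with a Bartlett
window $q(j) = 1 - j/L$, $L = \lceil 3 N_c^{0.3}\rceil$, standardized by
the $M_{N_c}(q)$, $V_{N_c}(q)$ functionals; under the null it is
asymptotically standard normal and the one-sided test rejects (declares
serial correlation) above $z_{1-\alpha}$, with $\alpha = 0.1$ by default —
a *stringent* choice, since rejection means misspecification. Two
implementation decisions:

* The printed index ranges for the lagged covariance would pair residuals
  beyond the epoch end; lag-$r$ products are taken over the valid
  within-epoch pairs $n = 1..N_j - r$, keeping the stated
  $N_c = \sum_j N_j - (J-1)L$ normalization. For $J > 1$, $L$ and $N_c$
  are mutually dependent; a fixed-point iteration from
  $L = \lceil 3 (\sum N_j)^{0.3}\rceil$ resolves both (for $J = 1$ this is
  exactly the printed rule).
* On residuals of an OLS *fit*, the statistic is badly conservative at
  realistic sample sizes: estimation absorbs chance-level residual
  autocorrelation, deflating the statistic by roughly
  $d^2\sum_{r\le p} q^2(r) / \sqrt{2 d^2 V}$ — about 2.5 null SDs at
  $N_c \approx 5000$, driving the type-I rate from 0.1 to ~0. Passing the
  fitted model (`fit =`) subtracts the asymptotic expected suppression
  $\delta_r = d\,\mathrm{tr}(Q^{-1} U_r G^{-1} U_r^T)$ (with
  $U_r = [Q\Psi_{r-1}^T,\dots,Q\Psi_{r-p}^T, 0]$ built from the model's
  impulse response $\Psi_k$ and $G$ the regressor covariance) from the
  centering term, and the matching degrees-of-freedom loss from the
  variance term. This is the kernel-test analog of the Ljung–Box $L-p$
  correction; for a scalar AR(1) it reduces to the classical
  $(1-a^2)a^{2(r-1)}$ profile. Monte-Carlo validation (500 correctly
  specified fits, $d=4$, $p=3$, $N_c=4990$): statistic mean ≈ 0, variance
  ≈ 0.99, rejection rate 0.094 at $\alpha = 0.1$. The uncorrected printed
  statistic remains available (`fit = NULL`) and is the right choice for
  raw, unfitted series.

**Fit metrics** (`fit_metrics`, `average_cv_responses`). Per-channel NMSD
(normalized mean-squared difference between the two-phase-averaged measured
and model responses), RRMS (channel energy relative to the strongest
channel), pooled NMRD, and the one-step NMSE whose numerator averages over
$n \ge n_0+1$ while the denominator uses all samples — so the zero model
has NMSE ≈ 1 on a stationary segment.

**Integrated information** (`phi_profile`). For the fitted model's AR part
(the stimulus filters only describe how input *enters* the network), the
stationary covariance $\Sigma$ solves the companion-form discrete Lyapunov
equation (solved by doubling — exact for stable systems and cheap at
$dp \le 120$) and lagged covariances $\Gamma_\tau$ follow the Yule–Walker
recursion. Effective information of a bipartition
$\mathcal B = \{M^1, M^2\}$ at lag $\tau$ is

$$\varphi(\tau,\mathcal B) = \tfrac12\Big[-\log_2 \det \Sigma(y_{n-\tau}\mid y_n)
 + \sum_i \log_2 \det \Sigma(m^i_{n-\tau}\mid m^i_n)\Big]\ \text{bits},$$

with conditional covariances $\Sigma - \Gamma_\tau \Sigma^{-1}
\Gamma_\tau^T$ from the *marginal* blocks (not refitted sub-models). The
minimum information bipartition minimizes $\varphi / K^2$ over all
$2^{d-1}-1$ bipartitions (exhaustive; the normalizer notation $K^2$ vs
$K_2$ in the source material is treated as one quantity), where $K^2$ is
the smaller part's differential entropy; integrated information
$\phi(\tau)$ is the *unnormalized* $\varphi$ at that partition. Since
differential entropy can be negative for low-variance parts, partitions
with $K^2 \le 0$ are excluded with a warning. $\phi$'s nonnegativity is a
KL-divergence argument, not asserted by the code: it is checked empirically
($\ge -10^{-9}$ over 1000 random stable systems). Profiles run over
$\tau = 1..30$ samples (10–300 ms at 100 Hz); conditions are compared by a
two-sided Wilcoxon rank-sum test on per-CV-partition maxima
(`compare_conditions`), exact for small tie-free samples.

## What the synthetic world does and does not emulate

`random_stable_mvarx()` draws i.i.d. Gaussian lag matrices and rescales
lag $i$ by $(\rho_\text{target}/\rho)^i$ — a similarity scaling of the
companion matrix, so the spectral radius hits the target exactly without
rejection sampling. $Q = WW^T + 0.1I$ is strictly PD and well conditioned.
Sessions follow the clinical protocol: 30 pulses at 1 s intervals, 0.2 ms
pulses at 1000 Hz (or generated directly at 100 Hz), 100-sample epochs
with 12 pre-stimulus samples. The stimulus gain default (`b_scale = 20`)
was calibrated once so the *true* model's one-step NMSE on a default
session is ≈ 0.05, matching the evoked-dominated regime the clinical
datasets report (NMSE ≤ 0.06); it was not chosen to satisfy any test.
Outlier epochs are epoch-length half-sines at 10 per-channel SDs (slow-wave
surrogates); raw sessions add ~9 ms raised-cosine conduction artifacts of
~50–100 SD at each pulse and a binary trigger channel.

Not emulated: 1/f spectral shape, line noise beyond what the lowpass
removes, epileptiform transients, inter-channel propagation delays other
than those an MVARX can express, and any electrode geometry. A green test
therefore establishes correctness of the *algorithms* under the model's
own assumptions, not fidelity to any particular brain.

Wake/sleep discrimination is exercised on two fixture families:
"wake-like" (dense coupling, spectral radius 0.85) and "sleep-like" (two
weakly coupled blocks, radius 0.92, 5% inter-block coupling). The
*direction* of the integrated-information difference is built into these
fixtures; what the test establishes is that the estimation + integration
pipeline separates regimes that differ in their coupling structure, with
the rank-sum contrast at $p < 0.05$ across 7 CV partitions.

## Numerical choices and degenerate inputs

* Stability gate: simulation and moments require spectral radius < 1.
* $Q = 0$ is legal for simulation (eigen-based PSD square root).
* Lyapunov doubling iterates to $\|F^{2^k}\| < 10^{-14}$; exact for the
  radii used here.
* Conditional-covariance determinants are computed by `determinant()`;
  a non-positive sign raises an error rather than returning NaN.
* MIB enumeration is guarded at $d \le 20$ (override `d_max`).
* Ties in the CV score and in `which.min`/`which.max` resolve to the
  smaller order / earlier lag.
* All-zero reference traces make the normalized metrics undefined and
  raise errors.
* With a *binary* impulse trigger and fixed stimulus-aligned epochs, input
  lags whose pulse samples all fall inside the $n_0$ initial-condition
  window (e.g. lag 0 once $p >$ the 12-sample pre-stimulus offset) have
  identically zero regressor rows; `mvarx_fit` drops them and zero-fills
  the corresponding $B$ coefficients instead of failing, since those
  coefficients are structurally unidentifiable from such epochs. (With the
  filtered trigger of the real preprocessing chain this degeneracy cannot
  arise.) Zero rows in the lagged-signal block still raise an error.
* JSON model files store 17 significant digits (lossless double
  round-trip).

## Known limitations

* Scalar exogenous input: one stimulation site per session; multi-input
  estimation is a deliberate non-goal.
* The estimation-df whiteness correction is asymptotic; at very small
  $N_c$ (a few hundred samples) calibration degrades for any version of
  this statistic.
* EDF import is not provided (no EDF reader in the supported dependency
  set); use CSV or HDF5.
* CV order selection is only as sharp as the data's high-lag content (see
  above); reported orders should be read as "effective memory", not
  ground truth.
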