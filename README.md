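# stimvarx

Multivariate autoregressive modeling with an exogenous stimulus input
(MVARX) for multichannel intracerebral recordings of responses to direct
electrical cortical stimulation.

## Who this is for

Electrophysiologists and methods researchers who record SEEG (or similar
multichannel) responses to single-pulse stimulation trains and want a
*stationary, generative* network model of the data — directed inter-site
coupling, per-site stimulus transmission filters, and innovation noise —
instead of subtracting the evoked mean or fitting time-varying models.
Everything in the package runs on synthetic data it can generate itself,
so the full pipeline is testable without clinical recordings.

## The model

Each d-channel sample is described by

    y[n] = sum_{i=1..p} A_i y[n-i] + sum_{i=0..l} b_i x[n-i] + w[n]

* `A_1..A_p` (d x d): directed coupling between recording sites; entry
  (m, k) of `A_i` is the influence of channel k on channel m at lag i.
* `B = [b_0..b_l]` (d x (l+1)): FIR filters from the stimulus trigger
  `x[n]` to each channel — direct propagation along fibers of passage.
  Default `l = 10` (100 ms at the 100 Hz analysis rate).
* `w[n] ~ N(0, Q)`: innovations generating spontaneous activity.

`Theta = [A, B]` and `Q` are estimated jointly by ordinary least squares
(the ML estimate under Gaussian noise). The AR order p is chosen by
cross-validation combining one-step prediction error with evoked-response
reconstruction error; residual whiteness is checked with a kernel-weighted
portmanteau test (Bartlett window, `L = ceil(3 Nc^0.3)`); and the fitted
network's Gaussian integrated information `phi(tau)` — effective
information at the minimum information bipartition — summarizes how far
the coupled system departs from its best split into independent parts.

Pipeline: artifact cleaning (Tukey-windowed median filter) -> lowpass +
downsample to 100 Hz -> stimulus-aligned epoching -> leave-one-out
Mahalanobis outlier rejection -> CV order selection -> OLS fit on maximum
contiguous segments -> whiteness test -> fit metrics (NMSD / RRMS / NMRD /
NMSE) -> phi profile. See `vignettes/stimvarx-methods.Rmd` for the methods
account.

## Worked example

```r
library(stimvarx)

truth   <- random_stable_mvarx(d = 6, p = 2, ell = 10,
                               spectral_radius = 0.85, seed = 7)
train   <- stim_train()                              # 30 pulses, 1 s apart
session <- simulate_session(truth, train, n_samples = 3012, seed = 8)
session <- inject_outliers(session, epoch_indices = 9, scale = 10, seed = 9)

epochs   <- segment_epochs(session)                  # 30 x 100-sample epochs
rej      <- reject_outliers(epochs)
rej$report
#> outlier_report: 1/30 epochs rejected (threshold 2678.5 = Nd + 60*sqrt(2Nd))
#>   rejected: 9  (D2 = 314109)

keep     <- subset_epochs(epochs, rej$report$retained)
segments <- merge_retained_epochs(epochs, rej$report$retained)

cv <- select_order(keep, p_grid = 1:8, ell = 10, M = 9)
cv
#> cv_result: selected p = 2 (grid 1..8, M = 9 partitions, ell = 10)
#>   weights: w_e = 34.87, w_eps = 32.51; min score = 1.9387

fit <- mvarx_fit(segments, cv$selected_p, ell = 10)
whiteness_test(mvarx_residuals(fit), alpha = 0.1, fit = fit)
#> whiteness_result: T = 0.879 vs z_0.9 = 1.282 -> residuals white (H0 retained)
#>   L = 33 lags (Bartlett), Nc = 2847 effective samples, d = 6

models <- lapply(cv$partition$train, function(tr)
  mvarx_fit(subset_epochs(keep, tr), cv$selected_p, 10))
avg <- average_cv_responses(keep, models, cv$partition)
fit_metrics(avg$measured, avg$modeled, fit, segments)
#> fit_metrics:
#>   NMSD per channel: 0.011 0.009 0.006 0.008 0.006 0.005
#>   RRMS per channel: 0.997 0.927 0.912 0.915 0.721 1.000
#>   NMRD (pooled) = 0.0076;  NMSE (one-step) = 0.0736

phi_profile(fit, tau_grid = 1:30)
#> phi_profile: 30 lags (10-300 ms); phi_max = 1.8733 bits at tau = 1 samples (10 ms)
```

Reading the numbers: the injected outlier epoch (#9) is the only one whose
leave-one-out Mahalanobis D² crosses the 60-SD threshold; cross-validation
recovers the generating order p = 2; the fitted residuals pass the
whiteness test (T below the 0.9 normal quantile), so the stationary MVARX
description is adequate; the averaged evoked response is reconstructed to
within ~1% energy per channel (NMSD), with one-step prediction explaining
~93% of signal energy (NMSE 0.074); and the fitted network's integrated
information (1.8733 bits) matches the generating model's (1.8734 bits).

`run_pipeline(pipeline_config(...))` chains the same stages end to end and
writes each stage's output (CSV/JSON + run log) to an output directory.

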