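#' Stimulation-artifact cleaning configuration
#'
#' Geometry of the Tukey-windowed median filter used to remove volume
#' conduction artifacts near each stimulus. The defaults reproduce the
#' standard 39 ms replacement window at 1000 Hz: the median-filtered signal
#' receives weight 1 within +/-10 ms of the stimulus, cosine tapers over
#' [10, 19] ms on both sides, and weight 0 at |t| >= 20 ms, where the raw
#' signal passes through untouched.
#'
#' @param median_order taps of the running median (odd, default 19).
#' @param flat_top_ms half-width of the unity-weight span (default 10).
#' @param taper_ms cosine taper duration in ms (default 9).
#' @return object of class `cleaning_config`.
#' @export
cleaning_config <- function(median_order = 19, flat_top_ms = 10, taper_ms = 9) {
  assert_scalar_num(median_order, "median_order", lower = 3)
  if (median_order %% 2 == 0) stopf("`median_order` must be odd")
  assert_scalar_num(flat_top_ms, "flat_top_ms", lower = 0)
  assert_scalar_num(taper_ms, "taper_ms", lower = 0)
  structure(list(median_order = as.integer(median_order),
                 flat_top_ms = flat_top_ms, taper_ms = taper_ms,
                 halfwidth_ms = flat_top_ms + taper_ms),
            class = "cleaning_config")
}

# Tukey weight sequence on sample offsets -hw..hw at rate fs
tukey_weights <- function(cfg, fs) {
  ms <- 1000 / fs
  hw <- ceiling(cfg$halfwidth_ms / ms)          # last nonzero offset
  t_ms <- abs(seq(-hw, hw)) * ms
  w <- numeric(length(t_ms))
  w[t_ms <= cfg$flat_top_ms] <- 1
  tp <- t_ms > cfg$flat_top_ms & t_ms < cfg$flat_top_ms + cfg$taper_ms + ms / 2
  w[tp] <- 0.5 * (1 + cos(pi * (t_ms[tp] - cfg$flat_top_ms) / cfg$taper_ms))
  w
}

#' Remove stimulation artifacts with a Tukey-windowed median filter
#'
#' Each channel is median filtered (order `cfg$median_order`); within a
#' window around every stimulus the output is the weighted average
#' `w * median + (1 - w) * raw`, with `w` a Tukey (cosine-tapered) window
#' that is 1 on the flat top, tapers to 0, and vanishes beyond the window
#' half-width. Samples outside every stimulus window are bit-identical to
#' the input.
#'
#' @param session raw-rate [session_data()].
#' @param trigger_times 1-based sample indices of stimuli at the raw rate;
#'   defaults to `session$truth$pulse_raw`, else to samples where
#'   `session$x` crosses 0.5.
#' @param cfg a [cleaning_config()].
#' @return cleaned `session_data` (same rate; `x` untouched).
#' @export
tukey_median_clean <- function(session, trigger_times = NULL,
                               cfg = cleaning_config()) {
  trigger_times <- trigger_times %||% session$truth$pulse_raw %||%
    which(session$x >= 0.5)
  T <- ncol(session$y)
  if (length(trigger_times) == 0L) return(session)
  if (any(trigger_times < 1L | trigger_times > T))
    stopf("trigger times out of bounds")
  w <- tukey_weights(cfg, session$fs)
  hw <- (length(w) - 1L) %/% 2L
  tt <- sort(as.integer(trigger_times))
  if (length(tt) > 1L && any(diff(tt) <= 2L * hw)) {
    bad <- which(diff(tt) <= 2L * hw)[1L]
    stopf("stimulus windows overlap: triggers at samples %d and %d are %d apart (< %d)",
          tt[bad], tt[bad + 1L], tt[bad + 1L] - tt[bad], 2L * hw + 1L)
  }
  y <- session$y
  for (i in seq_len(session$d)) {
    med <- stats::runmed(y[i, ], k = cfg$median_order, endrule = "median")
    for (t0 in tt) {
      idx <- (t0 - hw):(t0 + hw)
      keep <- idx >= 1L & idx <= T
      ii <- idx[keep]; wi <- w[keep]
      y[i, ii] <- wi * med[ii] + (1 - wi) * y[i, ii]
    }
  }
  session_data(y, session$x, session$fs, session$channel_names, session$truth)
}

#' Anti-alias filter / downsample configuration
#'
#' @param passband_hz passband edge (default 48 Hz, sparing activity below
#'   the post-downsampling Nyquist).
#' @param stopband_hz stopband edge (default 49.9 Hz, just under the 50 Hz
#'   powerline and the 50 Hz Nyquist after decimation by 10).
#' @param factor integer decimation factor (default 10).
#' @param atten_db minimum stopband attenuation of the FIR design
#'   (default 40 dB).
#' @return object of class `downsample_config`.
#' @export
downsample_config <- function(passband_hz = 48, stopband_hz = 49.9,
                              factor = 10, atten_db = 40) {
  assert_scalar_num(passband_hz, "passband_hz", lower = 1e-9)
  assert_scalar_num(stopband_hz, "stopband_hz", lower = passband_hz + 1e-9)
  assert_scalar_num(factor, "factor", lower = 1)
  assert_scalar_num(atten_db, "atten_db", lower = 1)
  structure(list(passband_hz = passband_hz, stopband_hz = stopband_hz,
                 factor = as.integer(factor), atten_db = atten_db),
            class = "downsample_config")
}

# Kaiser-window linear-phase FIR lowpass (odd length, unit DC gain).
# Standard Kaiser design: beta and length from the attenuation spec and
# transition width; cutoff at the band-edge midpoint.
fir_lowpass_kaiser <- function(fs, passband_hz, stopband_hz, atten_db = 40) {
  df <- (stopband_hz - passband_hz) / fs
  A <- atten_db
  beta <- if (A > 50) 0.1102 * (A - 8.7)
          else if (A >= 21) 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
          else 0
  M <- ceiling((A - 7.95) / (14.36 * df))
  if (M %% 2 == 1) M <- M + 1L                      # even order -> odd length
  n <- seq(0, M) - M / 2
  fc <- (passband_hz + stopband_hz) / 2 / fs        # normalized cutoff
  h <- 2 * fc * sinc(2 * fc * n)
  kw <- besselI(beta * sqrt(pmax(0, 1 - (2 * n / M)^2)), 0) / besselI(beta, 0)
  h <- h * kw
  h / sum(h)                                        # exact unity DC gain
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# zero-phase (group-delay compensated) FIR filtering with reflect padding
fir_filter_zerophase <- function(x, h) {
  M <- length(h) - 1L
  half <- M %/% 2L
  T <- length(x)
  pad <- min(half, T - 1L)
  xe <- c(rev(x[2:(pad + 1L)]), x, rev(x[(T - pad):(T - 1L)]))
  yf <- stats::convolve(xe, rev(h), type = "open")   # length T + 2*pad + M
  yf[(pad + half + 1L):(pad + half + T)]
}

#' Lowpass filter and downsample a session
#'
#' Applies a linear-phase FIR lowpass (Kaiser design meeting the
#' passband/stopband edges at the configured attenuation) with group-delay
#' compensation, then decimates. The exogenous input/trigger channel is
#' passed through the identical filter chain, so a binary trigger becomes a
#' smoothed pulse whose scale is absorbed by the estimated stimulus
#' filters; set `binary_trigger = TRUE` to bypass filtering of `x` and keep
#' pulses binary (purely synthetic workflows).
#'
#' @param session [session_data()] at the raw rate.
#' @param cfg a [downsample_config()].
#' @param binary_trigger if TRUE, `x` is decimated by pulse position
#'   without filtering.
#' @return `session_data` at `fs / factor`.
#' @export
antialias_downsample <- function(session, cfg = downsample_config(),
                                 binary_trigger = FALSE) {
  r <- cfg$factor
  if (ncol(session$y) %% r != 0)
    stopf("sample count %d not divisible by factor %d", ncol(session$y), r)
  fs_out <- session$fs / r
  if (cfg$stopband_hz > fs_out / 2 + 1e-9)
    stopf("stopband edge %g Hz exceeds post-decimation Nyquist %g Hz",
          cfg$stopband_hz, fs_out / 2)
  h <- fir_lowpass_kaiser(session$fs, cfg$passband_hz, cfg$stopband_hz, cfg$atten_db)
  keep <- seq(1L, ncol(session$y), by = r)
  y <- t(apply(session$y, 1L, function(ch) fir_filter_zerophase(ch, h)[keep]))
  if (binary_trigger) {
    x <- numeric(length(keep))
    pr <- which(session$x >= 0.5)
    x[(pr - 1L) %/% r + 1L] <- session$x[pr]
  } else {
    x <- fir_filter_zerophase(session$x, h)[keep]
  }
  tr <- session$truth
  if (!is.null(tr$pulse_raw)) tr$pulse_times <- (tr$pulse_raw - 1L) %/% r + 1L
  session_data(y, x, fs_out, session$channel_names, tr)
}

#' Segment a continuous recording into stimulus-aligned epochs
#'
#' Cuts fixed-length windows starting `pre` samples before each stimulus,
#' so the stimulus falls at within-epoch sample `pre + 1` (1-based). The
#' input sequence is segmented identically. With the defaults (pre = 12,
#' length = 100 at 100 Hz) each epoch spans 0.12 s pre-stimulus to 0.87 s
#' post-stimulus.
#'
#' @param session a [session_data()] at the analysis rate, or a `d x T`
#'   matrix (then pass `x` and `fs`).
#' @param stim_times 1-based stimulus sample indices at the analysis rate;
#'   defaults to the session truth train.
#' @param pre samples before the stimulus (default 12).
#' @param epoch_length epoch length in samples (default 100).
#' @param x,fs input vector and rate when `session` is a bare matrix.
#' @return an [epoch_set()] carrying `x_full` and `starts` for later evoked
#'   reconstruction.
#' @export
segment_epochs <- function(session, stim_times = NULL, pre = 12,
                           epoch_length = 100, x = NULL, fs = NULL) {
  if (inherits(session, "session_data")) {
    y <- session$y; x <- session$x; fs <- session$fs
    cn <- session$channel_names
    stim_times <- stim_times %||% session$truth$train$pulse_times
  } else {
    y <- as.matrix(session)
    if (is.null(x) || is.null(fs)) stopf("pass `x` and `fs` with a bare matrix")
    cn <- rownames(y) %||% paste0("ch", seq_len(nrow(y)))
  }
  if (is.null(stim_times) || length(stim_times) == 0L)
    stopf("no stimulus times available")
  if (is.unsorted(stim_times, strictly = TRUE)) stopf("`stim_times` must be strictly increasing")
  starts <- as.integer(stim_times) - as.integer(pre)
  ends <- starts + as.integer(epoch_length) - 1L
  if (any(starts < 1L) || any(ends > ncol(y)))
    stopf("epoch windows out of bounds (first start %d, last end %d, T = %d)",
          min(starts), max(ends), ncol(y))
  epochs <- lapply(seq_along(starts), function(j) y[, starts[j]:ends[j], drop = FALSE])
  inputs <- lapply(seq_along(starts), function(j) x[starts[j]:ends[j]])
  epoch_set(epochs, inputs, fs = fs, channel_names = cn,
            stim_offset = as.integer(pre) + 1L, x_full = x, starts = starts)
}
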