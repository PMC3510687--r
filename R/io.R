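#' Read / write a continuous session
#'
#' Two plain-data container dialects:
#' * **CSV** — one column per channel plus a `trigger` column, header row;
#'   the sampling rate lives in a sidecar `<path>.meta` key=value file
#'   (`fs=100`). Always available.
#' * **HDF5** — datasets `/y` (`d x T`), `/x` (length `T`), attributes
#'   `fs` and `channel_names`; requires the `rhdf5` package.
#'
#' @param path file path; format is inferred from the extension
#'   (`.h5`/`.hdf5` vs anything else) unless given.
#' @param format `"auto"`, `"csv"` or `"hdf5"`.
#' @return `read_session` returns a [session_data()]; `write_session`
#'   returns `path` invisibly.
#' @export
read_session <- function(path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "hdf5") {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stopf("reading HDF5 requires the `rhdf5` package")
    y <- rhdf5::h5read(path, "y")
    x <- as.numeric(rhdf5::h5read(path, "x"))
    fs <- as.numeric(rhdf5::h5read(path, "meta/fs"))
    cn <- as.character(rhdf5::h5read(path, "meta/channel_names"))
    rhdf5::h5closeAll()
    return(session_data(y, x, fs, cn))
  }
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"trigger" %in% names(tab))
    stopf("CSV must contain a `trigger` column (columns: %s)",
          paste(names(tab), collapse = ", "))
  x <- tab$trigger
  ych <- setdiff(names(tab), "trigger")
  y <- t(as.matrix(tab[ych]))
  dimnames(y) <- NULL
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stopf("missing sidecar metadata file %s (needs fs=)", meta_path)
  meta <- read_keyvals(meta_path)
  if (is.null(meta$fs)) stopf("sidecar %s lacks `fs`", meta_path)
  session_data(y, x, as.numeric(meta$fs), ych)
}

#' @rdname read_session
#' @param session a [session_data()].
#' @export
write_session <- function(session, path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "csv"
  if (format == "hdf5") {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stopf("writing HDF5 requires the `rhdf5` package")
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(session$y, path, "y")
    rhdf5::h5write(session$x, path, "x")
    rhdf5::h5createGroup(path, "meta")
    rhdf5::h5write(session$fs, path, "meta/fs")
    rhdf5::h5write(session$channel_names, path, "meta/channel_names")
    rhdf5::h5closeAll()
    return(invisible(path))
  }
  tab <- as.data.frame(t(session$y))
  names(tab) <- session$channel_names
  tab$trigger <- session$x
  utils::write.csv(tab, path, row.names = FALSE)
  writeLines(sprintf("fs=%.17g", session$fs), paste0(path, ".meta"))
  invisible(path)
}

read_keyvals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  vals
}

#' Pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Every tunable of the
#' pipeline stages is a field; unknown keys are rejected so typos fail
#' loudly.
#'
#' @param ... overrides for the defaults listed below.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = NULL,            # session file; NULL -> synthesize
    out_dir = "stimvarx-out",
    seed = 1L,
    # synthesis (used when input is NULL)
    synth_d = 8L, synth_p = 2L, synth_radius = 0.8,
    n_pulses = 30L, isi = 100L,
    # preprocessing
    raw = FALSE,             # TRUE: input is raw-rate, run clean + downsample
    median_order = 19L, flat_top_ms = 10, taper_ms = 9,
    passband_hz = 48, stopband_hz = 49.9, factor = 10L, atten_db = 40,
    binary_trigger = TRUE,
    # epoching / outliers
    pre = 12L, epoch_length = 100L, n_sd = 60,
    # order selection / fitting
    p_grid_max = 30L, ell = 10L, M = NA_integer_,
    # diagnostics / integration
    alpha = 0.1, tau_max = 30L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a key=value text file
#'
#' @param path text file with `key=value` lines (`#` comments allowed).
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- read_keyvals(path)
  proto <- unclass(pipeline_config())
  for (k in names(vals)) {
    if (!k %in% names(proto)) stopf("unknown config key: %s", k)
    tmpl <- proto[[k]]
    vals[[k]] <- if (is.logical(tmpl)) as.logical(vals[[k]])
      else if (is.integer(tmpl)) as.integer(vals[[k]])
      else if (is.numeric(tmpl)) as.numeric(vals[[k]])
      else vals[[k]]
  }
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: load or synthesize a session,
#' (optionally) clean stimulation artifacts and downsample, segment into
#' stimulus-aligned epochs, reject outlying epochs, select the AR order by
#' cross-validation, fit the MVARX model on merged contiguous segments,
#' test residual whiteness, compute evoked-response and prediction
#' metrics, and profile integrated information. Each stage's output is
#' written under `out_dir` as delimited text / JSON, together with a run
#' log recording the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisible list with every stage's result.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  train <- stim_train(n_pulses = config$n_pulses, isi = config$isi)
  if (is.null(config$input)) {
    say("synthesizing session (d = %d, p = %d)", config$synth_d, config$synth_p)
    truth <- random_stable_mvarx(config$synth_d, config$synth_p, config$ell,
                                 config$synth_radius, seed = config$seed)
    T <- max(train$pulse_times) + config$epoch_length
    session <- stage("synth", simulate_session(truth, train, T, seed = config$seed + 1L))
    write_mvarx(truth, file.path(config$out_dir, "truth_model.json"))
  } else {
    say("reading %s", config$input)
    session <- stage("read", read_session(config$input))
  }

  if (config$raw) {
    say("cleaning stimulation artifacts + downsampling")
    ccfg <- cleaning_config(config$median_order, config$flat_top_ms, config$taper_ms)
    dcfg <- downsample_config(config$passband_hz, config$stopband_hz,
                              config$factor, config$atten_db)
    session <- stage("preprocess", {
      cleaned <- tukey_median_clean(session, cfg = ccfg)
      antialias_downsample(cleaned, dcfg, binary_trigger = config$binary_trigger)
    })
  }

  say("epoching + outlier rejection")
  stim_times <- session$truth$train$pulse_times %||% session$truth$pulse_times %||%
    which(session$x >= 0.5)
  epochs <- stage("segment", segment_epochs(session, stim_times,
                                            pre = config$pre,
                                            epoch_length = config$epoch_length))
  rej <- stage("reject", reject_outliers(epochs, n_sd = config$n_sd))
  utils::write.csv(data.frame(epoch = seq_along(rej$report$d2),
                              d2 = rej$report$d2,
                              threshold = rej$report$threshold,
                              rejected = seq_along(rej$report$d2) %in% rej$report$rejected),
                   file.path(config$out_dir, "outliers.csv"), row.names = FALSE)

  say("cross-validated order selection")
  keep <- rej$report$retained
  cv_epochs <- subset_epochs(epochs, keep)
  M <- if (is.na(config$M)) max(2, round(length(keep) / 3)) else config$M
  cv <- stage("cv", select_order(cv_epochs, p_grid = seq_len(config$p_grid_max),
                                 ell = config$ell, M = M))
  utils::write.csv(data.frame(p = cv$p_grid, score = cv$score),
                   file.path(config$out_dir, "cv_scores.csv"), row.names = FALSE)

  say("fitting MVARX at p = %d on contiguous segments", cv$selected_p)
  segments <- stage("merge", merge_retained_epochs(epochs, keep))
  fit <- stage("fit", mvarx_fit(segments, cv$selected_p, config$ell))
  write_mvarx(fit, file.path(config$out_dir, "model.json"))

  say("residual whiteness test")
  wt <- stage("whiteness", whiteness_test(mvarx_residuals(fit), alpha = config$alpha,
                                          fit = fit))

  say("fit metrics")
  models <- lapply(seq_len(cv$partition$M), function(m)
    mvarx_fit(subset_epochs(cv_epochs, cv$partition$train[[m]]),
              cv$selected_p, config$ell))
  avg <- average_cv_responses(cv_epochs, models, cv$partition)
  met <- stage("metrics", fit_metrics(avg$measured, avg$modeled, fit, segments))

  say("integrated information profile")
  phi <- stage("phi", phi_profile(fit, tau_grid = seq_len(config$tau_max)))
  utils::write.csv(data.frame(tau = phi$taus, tau_ms = phi$tau_ms, phi = phi$phi),
                   file.path(config$out_dir, "phi_profile.csv"), row.names = FALSE)

  log <- c(sprintf("stimvarx %s", as.character(utils::packageVersion("stimvarx"))),
           sprintf("R %s", R.version.string),
           sprintf("seed=%d", config$seed),
           sprintf("selected_p=%d", cv$selected_p),
           sprintf("whiteness_T=%.6f reject=%s", wt$T, wt$reject),
           sprintf("nmrd=%.6f nmse=%.6f", met$nmrd, met$nmse),
           sprintf("phi_max=%.6f tau_argmax=%d", phi$phi_max, phi$tau_argmax),
           vapply(names(unclass(config)), function(k)
             sprintf("config.%s=%s", k, paste(format(config[[k]]), collapse = ",")),
             character(1)))
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  say("done; outputs in %s", config$out_dir)
  invisible(list(session = session, epochs = epochs, outliers = rej$report,
                 cv = cv, model = fit, whiteness = wt, metrics = met,
                 phi = phi, config = config))
}
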