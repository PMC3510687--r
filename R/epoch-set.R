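#' Epoched multichannel data with aligned exogenous input
#'
#' Container for `J` epochs of `d`-channel recordings `y` with
#' sample-aligned exogenous input sequences `x`. Epoch lengths `N_j` may
#' vary (model fitting uses maximum contiguous segments; outlier detection
#' and cross-validation use fixed-length 100-sample epochs). Optionally
#' carries the continuous session input `x_full` and per-epoch start
#' indices `starts` (1-based into the session) so that the model's evoked
#' response to the whole stimulus train can be reconstructed and sliced
#' epoch-wise.
#'
#' @param epochs list of `d x N_j` numeric matrices.
#' @param inputs list of length-`N_j` numeric vectors (exogenous input).
#' @param fs analysis sampling rate in Hz.
#' @param channel_names optional labels, length `d`.
#' @param stim_offset 1-based sample index of the stimulus within
#'   fixed-length epochs (13 for the default 12-sample pre-stimulus
#'   window), or `NA` for merged variable-length segments.
#' @param x_full optional continuous session input.
#' @param starts optional integer vector of epoch start indices into the
#'   session.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, inputs, fs = 100, channel_names = NULL,
                      stim_offset = NA_integer_, x_full = NULL, starts = NULL) {
  if (!is.list(epochs) || length(epochs) < 1L) stopf("`epochs` must be a non-empty list")
  epochs <- lapply(epochs, as.matrix)
  d <- nrow(epochs[[1L]])
  for (e in epochs) if (nrow(e) != d) stopf("all epochs must have %d channels", d)
  if (!is.list(inputs) || length(inputs) != length(epochs))
    stopf("`inputs` must be a list parallel to `epochs`")
  for (j in seq_along(epochs))
    if (length(inputs[[j]]) != ncol(epochs[[j]]))
      stopf("input %d has %d samples but epoch has %d", j,
            length(inputs[[j]]), ncol(epochs[[j]]))
  assert_scalar_num(fs, "fs", lower = 1e-12)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d))
  structure(list(epochs = epochs, inputs = inputs, fs = fs, d = d,
                 channel_names = channel_names, stim_offset = stim_offset,
                 x_full = x_full, starts = starts),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  Nj <- vapply(x$epochs, ncol, integer(1))
  cat(sprintf("epoch_set: %d epochs, d = %d channels, fs = %g Hz\n",
              length(x$epochs), x$d, x$fs))
  cat(sprintf("  epoch lengths: %s\n",
              if (length(unique(Nj)) == 1L) sprintf("%d samples each", Nj[1])
              else sprintf("%d..%d samples (variable)", min(Nj), max(Nj))))
  invisible(x)
}

n_epochs <- function(es) length(es$epochs)
epoch_lengths <- function(es) vapply(es$epochs, ncol, integer(1))

#' Subset an epoch set by epoch index, keeping session-level metadata
#'
#' @param es an [epoch_set()].
#' @param idx epoch indices to keep.
#' @return an [epoch_set()].
#' @export
subset_epochs <- function(es, idx) {
  epoch_set(es$epochs[idx], es$inputs[idx], fs = es$fs,
            channel_names = es$channel_names, stim_offset = es$stim_offset,
            x_full = es$x_full, starts = es$starts[idx])
}
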