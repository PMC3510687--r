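#' Leave-one-out ensemble moments of an epoch set
#'
#' Time-varying mean and covariance of the epoch ensemble computed with
#' epoch `m` excluded:
#' \deqn{\mu^{-m}(n) = \frac{1}{J-1}\sum_{j \ne m} y_n^{(j)}, \qquad
#'       \Sigma^{-m}(n) = \frac{1}{J-2}\sum_{j \ne m}
#'       (y_n^{(j)}-\mu^{-m}(n))(y_n^{(j)}-\mu^{-m}(n))^T.}
#'
#' @param epochs an [epoch_set()] of `J >= 3` equal-length epochs.
#' @param m epoch index to exclude.
#' @return list with `mean` (`d x N`) and `cov` (`d x d x N`).
#' @export
loo_moments <- function(epochs, m) {
  J <- n_epochs(epochs)
  if (J < 3L) stopf("need J >= 3 epochs (covariance divides by J - 2)")
  Nj <- epoch_lengths(epochs)
  if (length(unique(Nj)) != 1L) stopf("all epochs must have equal length")
  if (m < 1L || m > J) stopf("`m` must be in 1..%d", J)
  N <- Nj[1L]; d <- epochs$d
  others <- setdiff(seq_len(J), m)
  mu <- matrix(0, d, N)
  for (j in others) mu <- mu + epochs$epochs[[j]]
  mu <- mu / (J - 1L)
  S <- array(0, c(d, d, N))
  for (j in others) {
    Dev <- epochs$epochs[[j]] - mu
    for (n in seq_len(N)) S[, , n] <- S[, , n] + tcrossprod(Dev[, n])
  }
  list(mean = mu, cov = S / (J - 2L))
}

# inverse with diagonal loading when badly conditioned
robust_inverse <- function(S, lambda = 1e-6, cond_max = 1e10) {
  ev <- eigen(symm(S), symmetric = TRUE, only.values = TRUE)$values
  loaded <- FALSE
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > cond_max) {
    S <- S + lambda * (sum(diag(S)) / nrow(S)) * diag(nrow(S))
    loaded <- TRUE
  }
  list(inv = solve(symm(S)), loaded = loaded)
}

#' Leave-one-out squared Mahalanobis distance of one epoch
#'
#' \deqn{D^2(m) = \sum_{n=1}^{N} (y_n^{(m)}-\mu^{-m}(n))^T
#'   (\Sigma^{-m}(n))^{-1} (y_n^{(m)}-\mu^{-m}(n)).}
#' For Gaussian data this is approximately chi-squared with `N * d` degrees
#' of freedom. With few epochs relative to `d` the per-sample covariance is
#' ill conditioned; diagonal loading `lambda * tr(S)/d * I` is applied
#' whenever the condition number exceeds `1e10` (a message reports how many
#' samples were loaded).
#'
#' @inheritParams loo_moments
#' @param regularize apply diagonal loading when needed (default TRUE;
#'   FALSE errors on singular covariance).
#' @return nonnegative scalar `D^2(m)`.
#' @export
mahalanobis_d2 <- function(epochs, m, regularize = TRUE) {
  mom <- loo_moments(epochs, m)
  Y <- epochs$epochs[[m]]
  N <- ncol(Y)
  d2 <- 0
  n_loaded <- 0L
  for (n in seq_len(N)) {
    S <- mom$cov[, , n, drop = TRUE]
    if (epochs$d == 1L) S <- matrix(S, 1L, 1L)
    if (!regularize) {
      ri <- tryCatch(list(inv = solve(symm(S)), loaded = FALSE),
                     error = function(e) stopf(
                       "singular covariance at sample %d; enable `regularize`", n))
    } else ri <- robust_inverse(S)
    if (ri$loaded) n_loaded <- n_loaded + 1L
    v <- Y[, n] - mom$mean[, n]
    d2 <- d2 + drop(crossprod(v, ri$inv %*% v))
  }
  if (n_loaded > 0L)
    message(sprintf("mahalanobis_d2: diagonal loading applied at %d/%d samples", n_loaded, N))
  max(d2, 0)
}

#' Reject outlying epochs by leave-one-out Mahalanobis distance
#'
#' Epoch `m` is rejected when `D^2(m)` exceeds `N*d + n_sd * sqrt(2*N*d)`
#' — the chi-squared mean plus `n_sd` standard deviations (default 60, a
#' deliberately permissive threshold that only removes gross deviations
#' such as sleep slow waves). With the standard 100-sample epochs the
#' threshold is `100 d + 60 sqrt(2 * 100 * d)`.
#'
#' @inheritParams loo_moments
#' @param n_sd threshold multiplier (default 60).
#' @param regularize see [mahalanobis_d2()].
#' @return list with `epochs` (the retained [epoch_set()]) and `report`
#'   (class `outlier_report`: `d2`, `threshold`, `retained`, `rejected`).
#' @export
reject_outliers <- function(epochs, n_sd = 60, regularize = TRUE) {
  J <- n_epochs(epochs)
  N <- epoch_lengths(epochs)[1L]
  d2 <- vapply(seq_len(J), function(m) mahalanobis_d2(epochs, m, regularize),
               numeric(1))
  thr <- N * epochs$d + n_sd * sqrt(2 * N * epochs$d)
  rejected <- which(d2 > thr)
  retained <- setdiff(seq_len(J), rejected)
  if (length(retained) == 0L) stopf("all epochs rejected; nothing left to analyze")
  report <- structure(list(d2 = d2, threshold = thr, n_sd = n_sd,
                           retained = retained, rejected = rejected),
                      class = "outlier_report")
  list(epochs = subset_epochs(epochs, retained), report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d/%d epochs rejected (threshold %.1f = Nd + %g*sqrt(2Nd))\n",
              length(x$rejected), length(x$d2), x$threshold, x$n_sd))
  if (length(x$rejected))
    cat("  rejected:", paste(x$rejected, collapse = ", "),
        sprintf(" (D2 = %s)\n", paste(sprintf("%.0f", x$d2[x$rejected]), collapse = ", ")))
  invisible(x)
}

#' Merge surviving epochs into maximum contiguous segments
#'
#' After outlier rejection, model fitting uses the maximum contiguous
#' stretches of data between removed segments, which minimizes the samples
#' lost to initial conditions at segment starts. Adjacent retained epochs
#' whose session windows abut are concatenated into one variable-length
#' segment.
#'
#' @param epochs the fixed-length [epoch_set()] that was screened (must
#'   carry `starts`).
#' @param retained indices of retained epochs (e.g. from the report).
#' @return a variable-length [epoch_set()] of contiguous segments.
#' @export
merge_retained_epochs <- function(epochs, retained) {
  if (is.null(epochs$starts)) stopf("`epochs` lacks session start indices")
  retained <- sort(retained)
  N <- epoch_lengths(epochs)[1L]
  starts <- epochs$starts[retained]
  brk <- c(TRUE, diff(starts) != N)        # TRUE where a new segment begins
  grp <- cumsum(brk)
  segs <- split(retained, grp)
  eps <- lapply(segs, function(ix) do.call(cbind, epochs$epochs[ix]))
  ins <- lapply(segs, function(ix) unlist(epochs$inputs[ix], use.names = FALSE))
  epoch_set(eps, ins, fs = epochs$fs, channel_names = epochs$channel_names,
            stim_offset = NA_integer_, x_full = epochs$x_full,
            starts = vapply(segs, function(ix) epochs$starts[ix[1L]], integer(1)))
}
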