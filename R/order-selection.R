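#' Contiguous cross-validation partition of epochs
#'
#' Splits `J` epochs into `M` non-overlapping test sets of contiguous
#' epochs with sizes differing by at most one; the training set of
#' partition `m` is the complement. Contiguous blocks (rather than random
#' draws) make every test set span roughly the same stretch of time, which
#' matters when the underlying state drifts (e.g. across vigilance
#' states). Deterministic in `(J, M)`.
#'
#' @param J number of epochs.
#' @param M number of partitions, `2 <= M <= J`. Default: about one test
#'   block per 3 epochs (`max(2, round(J/3))`).
#' @return object of class `cv_partition`: list with `test` and `train`
#'   lists of index vectors.
#' @export
partition_cv <- function(J, M = max(2, round(J / 3))) {
  assert_scalar_num(J, "J", lower = 2)
  assert_scalar_num(M, "M", lower = 2, upper = J)
  M <- as.integer(M)
  sizes <- rep(J %/% M, M)
  extra <- J %% M
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  test <- lapply(seq_len(M), function(m) (ends[m] - sizes[m] + 1L):ends[m])
  train <- lapply(test, function(s) setdiff(seq_len(J), s))
  structure(list(test = test, train = train, J = as.integer(J), M = M),
            class = "cv_partition")
}

# model's average response over test epochs: drive the whole session input
# through the model (state carried across pulses) and average the slices
# belonging to the test set
model_average_response <- function(model, epochs, test_idx) {
  if (is.null(epochs$x_full) || is.null(epochs$starts))
    stopf("`epochs` must carry x_full/starts (use segment_epochs())")
  N <- epoch_lengths(epochs)[1L]
  y_e <- simulate_evoked(model, epochs$x_full)
  acc <- matrix(0, epochs$d, N)
  for (j in test_idx) {
    s <- epochs$starts[j]
    acc <- acc + y_e[, s:(s + N - 1L), drop = FALSE]
  }
  acc / length(test_idx)
}

measured_average_response <- function(epochs, test_idx) {
  Reduce(`+`, epochs$epochs[test_idx]) / length(test_idx)
}

#' Cross-validation error components for one partition
#'
#' Fits the model on the training epochs and evaluates two errors on the
#' test set: `CV_e`, the mean square one-step prediction error
#' (per-epoch averages of `||e_n||^2` over `n = n0+1..N_j`, averaged over
#' test epochs), and `CV_eps`, the mean square average-response error —
#' the squared distance between the measured average response over the
#' test set and the model's average response, the latter computed by
#' presenting the entire session stimulus train to the model so that
#' carry-over from preceding pulses is reproduced.
#'
#' @param epochs fixed-length [epoch_set()] carrying `x_full`/`starts`.
#' @param p,ell model orders.
#' @param train_idx,test_idx epoch index vectors.
#' @return named numeric vector `c(cv_e, cv_eps)`.
#' @export
cv_components <- function(epochs, p, ell, train_idx, test_idx) {
  if (length(test_idx) == 0L) stopf("empty test set")
  fit <- mvarx_fit(subset_epochs(epochs, train_idx), p, ell)
  osp <- one_step_predict(fit, subset_epochs(epochs, test_idx))
  cv_e <- mean(vapply(osp$residuals, function(E) mean(colSums(E^2)), numeric(1)))
  ybar <- measured_average_response(epochs, test_idx)
  yhat <- model_average_response(fit, epochs, test_idx)
  cv_eps <- mean(colSums((ybar - yhat)^2))
  c(cv_e = cv_e, cv_eps = cv_eps)
}

#' Select the autoregressive order by weighted cross-validation
#'
#' For every candidate order `p` and partition `m`, computes the one-step
#' error `CV_e(p, m)` and average-response error `CV_eps(p, m)`; sets the
#' weights `w_e` and `w_eps` to the medians of the respective error
#' surfaces over all `(p, m)` (so the two error types get roughly equal
#' emphasis); and picks the `p` minimizing
#' \deqn{CV(p) = \frac{1}{M}\sum_m \Big[\frac{CV_e(p,m)}{w_e}
#'   + \frac{CV_\epsilon(p,m)}{w_\epsilon}\Big],}
#' ties broken toward the smaller order.
#'
#' @param epochs fixed-length [epoch_set()] with `x_full`/`starts`.
#' @param p_grid candidate AR orders (default 1:30).
#' @param ell exogenous order (default 10, fixed by the expected 100 ms
#'   direct-propagation duration at 100 Hz).
#' @param M number of CV partitions (default about J/3 test blocks).
#' @param partition optional precomputed [partition_cv()].
#' @return object of class `cv_result`: matrices `cv_e`, `cv_eps`
#'   (`M x |grid|`), weights, per-order `score`, `selected_p`, and the
#'   partition.
#' @export
select_order <- function(epochs, p_grid = 1:30, ell = 10, M = NULL,
                         partition = NULL) {
  if (length(p_grid) == 0L) stopf("empty order grid")
  p_grid <- sort(unique(as.integer(p_grid)))
  J <- n_epochs(epochs)
  partition <- partition %||% partition_cv(J, M %||% max(2, round(J / 3)))
  M <- partition$M
  n0_max <- max(max(p_grid), ell)
  min_train <- min(epoch_lengths(epochs))
  if (min_train < n0_max + 1L)
    stopf("largest order infeasible: epochs of %d samples < n0 + 1 = %d",
          min_train, n0_max + 1L)
  cv_e <- matrix(NA_real_, M, length(p_grid),
                 dimnames = list(NULL, paste0("p", p_grid)))
  cv_eps <- cv_e
  for (k in seq_along(p_grid)) for (m in seq_len(M)) {
    comp <- cv_components(epochs, p_grid[k], ell,
                          partition$train[[m]], partition$test[[m]])
    cv_e[m, k] <- comp["cv_e"]; cv_eps[m, k] <- comp["cv_eps"]
  }
  w_e <- stats::median(cv_e)
  w_eps <- stats::median(cv_eps)
  if (!is.finite(w_e) || w_e <= 0) w_e <- 1
  if (!is.finite(w_eps) || w_eps <= 0) w_eps <- 1
  score <- colMeans(cv_e / w_e + cv_eps / w_eps)
  structure(list(cv_e = cv_e, cv_eps = cv_eps, w_e = w_e, w_eps = w_eps,
                 score = score, p_grid = p_grid,
                 selected_p = p_grid[which.min(score)], ell = ell,
                 partition = partition),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: selected p = %d (grid %d..%d, M = %d partitions, ell = %d)\n",
              x$selected_p, min(x$p_grid), max(x$p_grid), x$partition$M, x$ell))
  cat(sprintf("  weights: w_e = %.4g, w_eps = %.4g; min score = %.4f\n",
              x$w_e, x$w_eps, min(x$score)))
  invisible(x)
}
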