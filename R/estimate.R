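#' Regression blocks for MVARX least squares
#'
#' Rewrites the MVARX model in linear-regression form
#' `y_n = Theta z_{n-1} + w_n` with
#' `z_{n-1} = [y_{n-1}', ..., y_{n-p}', x_n, x_{n-1}, ..., x_{n-ell}]'`
#' (the current input `x_n` enters at lag 0). The first
#' `n0 = max(p, ell)` samples of each epoch serve as initial conditions, so
#' epoch `j` contributes columns for `n = n0+1 .. N_j`.
#'
#' @param epochs an [epoch_set()]; every epoch must satisfy `N_j >= n0+1`.
#' @param p AR order.
#' @param ell exogenous filter order.
#' @return list with `Y`, `Z` (per-epoch column blocks; `Z` rows number
#'   `d*p + ell + 1`), `n0`, `Nt = sum(N_j) - n0*J`.
#' @export
build_regression <- function(epochs, p, ell) {
  d <- epochs$d
  n0 <- max(p, ell)
  Nj <- epoch_lengths(epochs)
  short <- which(Nj < n0 + 1L)
  if (length(short))
    stopf("epoch(s) %s shorter than n0 + 1 = %d samples",
          paste(short, collapse = ", "), n0 + 1L)
  Y <- vector("list", n_epochs(epochs))
  Z <- vector("list", n_epochs(epochs))
  for (j in seq_len(n_epochs(epochs))) {
    y <- epochs$epochs[[j]]
    x <- epochs$inputs[[j]]
    ns <- (n0 + 1L):Nj[j]
    Y[[j]] <- y[, ns, drop = FALSE]
    Zj <- matrix(0, d * p + ell + 1L, length(ns))
    for (i in seq_len(p))
      Zj[((i - 1L) * d + 1L):(i * d), ] <- y[, ns - i, drop = FALSE]
    for (i in 0:ell)
      Zj[d * p + i + 1L, ] <- x[ns - i]
    Z[[j]] <- Zj
  }
  list(Y = Y, Z = Z, n0 = n0, Nt = sum(Nj) - n0 * n_epochs(epochs))
}

#' Fit an MVARX model by ordinary least squares
#'
#' Jointly estimates the connectivity matrices `A_1..A_p`, the stimulus
#' filter bank `B` and the innovation covariance `Q` by OLS on the pooled
#' regression blocks:
#' \deqn{\hat\Theta = \Big(\sum_j Y_j Z_j^T\Big)\Big(\sum_j Z_j Z_j^T\Big)^{-1},
#'   \qquad \hat Q = \frac{1}{N_t}\sum_j (Y_j-\hat\Theta Z_j)(Y_j-\hat\Theta Z_j)^T.}
#' Under Gaussian innovations this is also the maximum-likelihood estimate.
#' The solve uses a QR factorization of the stacked regressors rather than
#' forming the normal equations, which tolerates the ill conditioning that
#' arises at high AR orders.
#'
#' @inheritParams build_regression
#' @return a fitted [mvarx_model()] with attributes `residuals` (per-epoch
#'   `d x (N_j - n0)` residual blocks), `n0` and `Nt` accessible via
#'   [mvarx_residuals()].
#' @export
mvarx_fit <- function(epochs, p, ell = 10) {
  reg <- build_regression(epochs, p, ell)
  Zall <- do.call(cbind, reg$Z)
  Yall <- do.call(cbind, reg$Y)
  # With a binary impulse trigger, input lags whose pulse samples all fall
  # inside the n0 initial-condition window have identically zero regressor
  # rows (unidentifiable); drop them and zero-fill the corresponding B
  # coefficients. Zero rows in the y-block indicate degenerate data and
  # remain an error.
  xrows <- (nrow(Zall) - ell):nrow(Zall)
  zero_rows <- which(apply(Zall, 1L, function(r) all(r == 0)))
  drop_x <- intersect(zero_rows, xrows)
  kept <- setdiff(seq_len(nrow(Zall)), drop_x)
  qrz <- qr(t(Zall[kept, , drop = FALSE]))
  if (qrz$rank < length(kept))
    stopf(paste0("regressors are rank deficient (rank %d < %d); ",
                 "reduce p/ell or provide more data"), qrz$rank, length(kept))
  Theta <- matrix(0, epochs$d, nrow(Zall))
  Theta[, kept] <- t(qr.coef(qrz, t(Yall)))
  resid_all <- Yall - Theta %*% Zall
  Q <- tcrossprod(resid_all) / reg$Nt
  d <- epochs$d
  A <- lapply(seq_len(p), function(i) Theta[, ((i - 1L) * d + 1L):(i * d), drop = FALSE])
  B <- Theta[, (d * p + 1L):(d * p + ell + 1L), drop = FALSE]
  fit <- mvarx_model(A, B, symm(Q), fs = epochs$fs,
                     channel_names = epochs$channel_names)
  ncols <- vapply(reg$Y, ncol, integer(1))
  splits <- rep(seq_along(ncols), ncols)
  attr(fit, "residuals") <- lapply(seq_along(ncols), function(j)
    resid_all[, splits == j, drop = FALSE])
  attr(fit, "n0") <- reg$n0
  attr(fit, "Nt") <- reg$Nt
  attr(fit, "regressor_cov") <- tcrossprod(Zall[kept, , drop = FALSE]) / reg$Nt
  attr(fit, "regressor_rows") <- kept
  fit
}

#' Residual blocks of a fitted model
#'
#' @param fit a model returned by [mvarx_fit()].
#' @return list of per-epoch residual matrices (`d x (N_j - n0)`).
#' @export
mvarx_residuals <- function(fit) {
  r <- attr(fit, "residuals")
  if (is.null(r)) stopf("model carries no residuals; fit it with mvarx_fit()")
  r
}

#' One-step prediction and residuals
#'
#' Predicts `y_n` from the regressor `z_{n-1}` (past measurements plus
#' current and past inputs) for `n = n0+1 .. N_j` in every epoch:
#' `yhat_n = Theta z_{n-1}`, residual `e_n = y_n - yhat_n`. When applied
#' with the same model and data used in fitting, the residuals equal the
#' OLS residual blocks.
#'
#' @param model an `mvarx_model`.
#' @param epochs an [epoch_set()].
#' @return list with `predictions` and `residuals` (per-epoch
#'   `d x (N_j - n0)` matrices) and `n0`.
#' @export
one_step_predict <- function(model, epochs) {
  reg <- build_regression(epochs, model$p, model$ell)
  Theta <- cbind(do.call(cbind, model$A), model$B)
  pred <- lapply(reg$Z, function(Zj) Theta %*% Zj)
  resid <- lapply(seq_along(pred), function(j) reg$Y[[j]] - pred[[j]])
  list(predictions = pred, residuals = resid, n0 = reg$n0)
}

#' Evoked/spontaneous decomposition of a recording
#'
#' Splits a continuous recording into the deterministic evoked component
#' `y_e` (the model driven by the stimulus from zero initial conditions)
#' and the spontaneous remainder `y_s = y - y_e`. On synthetic data
#' generated by [simulate_session()] with the true model, `y_e` matches the
#' stored truth exactly.
#'
#' @param model an `mvarx_model`.
#' @param session a [session_data()] (or a `d x T` matrix plus `x`).
#' @param x input vector when `session` is a bare matrix.
#' @return list with `evoked` and `spontaneous` (`d x T` matrices).
#' @export
mvarx_decompose <- function(model, session, x = NULL) {
  if (inherits(session, "session_data")) {
    y <- session$y; x <- session$x
  } else y <- as.matrix(session)
  if (is.null(x)) stopf("input `x` required")
  y_e <- simulate_evoked(model, x)
  list(evoked = y_e, spontaneous = y - y_e)
}

#' Fit an unconnected (channel-wise univariate ARX) comparison model
#'
#' Fits each channel independently as a univariate ARX model of the same
#' orders and assembles the results into a single `mvarx_model` with
#' diagonal lag matrices and diagonal `Q`. Used to quantify how much of the
#' data demands genuine inter-channel coupling: on coupled data this model
#' fails the residual whiteness test that the full fit passes.
#'
#' @inheritParams build_regression
#' @return an `mvarx_model` with per-channel residuals attached.
#' @export
fit_unconnected <- function(epochs, p, ell = 10) {
  d <- epochs$d
  A <- lapply(seq_len(p), function(i) matrix(0, d, d))
  B <- matrix(0, d, ell + 1L)
  Q <- matrix(0, d, d)
  res <- NULL
  for (i in seq_len(d)) {
    ei <- epoch_set(lapply(epochs$epochs, function(e) e[i, , drop = FALSE]),
                    epochs$inputs, fs = epochs$fs,
                    channel_names = epochs$channel_names[i])
    fi <- mvarx_fit(ei, p, ell)
    for (k in seq_len(p)) A[[k]][i, i] <- fi$A[[k]][1L, 1L]
    B[i, ] <- fi$B[1L, ]
    Q[i, i] <- fi$Q[1L, 1L]
    ri <- mvarx_residuals(fi)
    if (is.null(res)) res <- ri
    else res <- lapply(seq_along(res), function(j) rbind(res[[j]], ri[[j]]))
  }
  fit <- mvarx_model(A, B, Q, fs = epochs$fs, channel_names = epochs$channel_names)
  attr(fit, "residuals") <- res
  attr(fit, "n0") <- max(p, ell)
  fit
}
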