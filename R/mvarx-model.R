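#' MVARX model object
#'
#' Constructs a multivariate autoregressive model with exogenous input
#' (MVARX) of order \eqn{(p, \ell)}:
#' \deqn{y_n = \sum_{i=1}^{p} A_i y_{n-i} + \sum_{i=0}^{\ell} b_i x_{n-i} + w_n,}
#' where \eqn{y_n} is the \eqn{d}-channel recording, \eqn{x_n} a scalar
#' exogenous (stimulus) input and \eqn{w_n} zero-mean innovation noise with
#' covariance \eqn{Q}. Entry \eqn{[A_i]_{m,n}} is the influence of channel
#' \eqn{n} on channel \eqn{m} at lag \eqn{i}; row \eqn{i} of
#' \eqn{B = [b_0, \dots, b_\ell]} is the FIR filter from the stimulus to
#' channel \eqn{i} (direct propagation, e.g. via fibers of passage).
#'
#' @param A list of `p` square `d x d` lag matrices.
#' @param B `d x (ell+1)` matrix of exogenous input filter coefficients
#'   (columns are lags `0..ell`).
#' @param Q `d x d` symmetric positive semidefinite innovation covariance.
#' @param fs sampling rate in Hz of the analysis-rate data the model refers to.
#' @param channel_names optional character vector of length `d`.
#' @return an object of class `mvarx_model` with fields `A`, `B`, `Q`,
#'   `d`, `p`, `ell`, `fs`, `channel_names`.
#' @seealso [mvarx_fit()], [simulate_session()], [spectral_radius()]
#' @export
mvarx_model <- function(A, B, Q, fs = 100, channel_names = NULL) {
  if (is.matrix(A)) A <- list(A)
  if (!is.list(A) || length(A) < 1L) stopf("`A` must be a non-empty list of d x d matrices")
  d <- nrow(A[[1L]])
  for (Ai in A)
    if (!is.matrix(Ai) || any(dim(Ai) != d)) stopf("all `A` blocks must be %d x %d", d, d)
  B <- as.matrix(B)
  if (nrow(B) != d) stopf("`B` must have d = %d rows", d)
  Q <- symm(as.matrix(Q))
  if (any(dim(Q) != d)) stopf("`Q` must be %d x %d", d, d)
  if (min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values) < -1e-8 * max(1, max(abs(Q))))
    stopf("`Q` must be positive semidefinite")
  assert_scalar_num(fs, "fs", lower = 1e-12)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d))
  structure(list(A = A, B = B, Q = Q, d = d, p = length(A),
                 ell = ncol(B) - 1L, fs = fs, channel_names = channel_names),
            class = "mvarx_model")
}

#' @export
print.mvarx_model <- function(x, ...) {
  cat(sprintf("MVARX model: d = %d channels, p = %d AR lags, ell = %d input lags, fs = %g Hz\n",
              x$d, x$p, x$ell, x$fs))
  cat(sprintf("  spectral radius: %.4f (%s)\n", spectral_radius(x),
              if (spectral_radius(x) < 1) "stable" else "UNSTABLE"))
  cat(sprintf("  tr(Q) = %.4g\n", sum(diag(x$Q))))
  invisible(x)
}

#' Companion matrix of the autoregressive part
#'
#' Stacks the AR lag matrices into the `dp x dp` block companion form whose
#' first block row is `[A_1, ..., A_p]` and whose subdiagonal blocks are
#' identities, so the p-lag system becomes first order.
#'
#' @param model an `mvarx_model` (or a list of d x d lag matrices).
#' @return a `dp x dp` matrix.
#' @export
companion_matrix <- function(model) {
  A <- if (inherits(model, "mvarx_model")) model$A else model
  d <- nrow(A[[1L]]); p <- length(A)
  F <- matrix(0, d * p, d * p)
  for (i in seq_len(p)) F[1:d, ((i - 1L) * d + 1L):(i * d)] <- A[[i]]
  if (p > 1L) F[(d + 1L):(d * p), 1L:(d * (p - 1L))] <- diag(d * (p - 1L))
  F
}

#' Spectral radius of an MVARX model
#'
#' Largest eigenvalue magnitude of the companion matrix of the AR
#' coefficients; the model is stable (wide-sense stationary spontaneous
#' component) iff this is < 1.
#'
#' @param model an `mvarx_model`.
#' @return nonnegative scalar.
#' @export
spectral_radius <- function(model) {
  F <- companion_matrix(model)
  if (all(F == 0)) return(0)
  max(Mod(eigen(F, only.values = TRUE)$values))
}

#' Deterministic evoked response of an MVARX model
#'
#' Drives the model with the full stimulus sequence from zero initial
#' conditions and no innovation noise:
#' \deqn{y_{n,e} = \sum_{i=1}^{p} A_i y_{n-i,e} + \sum_{i=0}^{\ell} b_i x_{n-i}.}
#' State is carried across the whole sequence, so responses to earlier
#' pulses that outlast the inter-stimulus interval contribute to later
#' epochs, as in the measured data.
#'
#' @param model an `mvarx_model`.
#' @param x numeric vector, the exogenous input over the whole session.
#' @return `d x length(x)` matrix of the evoked component.
#' @export
simulate_evoked <- function(model, x) {
  d <- model$d; p <- model$p; ell <- model$ell
  T <- length(x)
  y <- matrix(0, d, T)
  Bx <- drive_input(model$B, x)               # d x T exogenous drive
  anyA <- any(vapply(model$A, function(M) any(M != 0), logical(1)))
  if (!anyA) return(Bx)
  for (n in seq_len(T)) {
    acc <- Bx[, n]
    for (i in seq_len(min(p, n - 1L)))
      acc <- acc + model$A[[i]] %*% y[, n - i]
    y[, n] <- acc
  }
  y
}

# FIR term sum_{i=0}^{ell} b_i x_{n-i} for all n (zero x before start)
drive_input <- function(B, x) {
  d <- nrow(B); ell <- ncol(B) - 1L; T <- length(x)
  out <- matrix(0, d, T)
  for (i in 0:ell) {
    if (all(B[, i + 1L] == 0)) next
    idx <- (i + 1L):T
    if (length(idx)) out[, idx] <- out[, idx] + outer(B[, i + 1L], x[idx - i])
  }
  out
}

#' Write / read an MVARX model as JSON
#'
#' Structured-text serialization: fields `d`, `p`, `ell`, `fs`,
#' `channel_names`, `A` (list of p row-major d x d blocks), `B` (d rows of
#' ell+1 coefficients), `Q` (row-major). Round-trips at full double
#' precision.
#'
#' @param model an `mvarx_model`.
#' @param path file path.
#' @return `write_mvarx` returns `path` invisibly; `read_mvarx` returns the
#'   model.
#' @export
write_mvarx <- function(model, path) {
  obj <- list(
    d = model$d, p = model$p, ell = model$ell, fs = model$fs,
    channel_names = model$channel_names,
    A = lapply(model$A, function(M) as.vector(t(M))),   # row-major
    B = as.vector(t(model$B)),
    Q = as.vector(t(model$Q)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_mvarx
#' @export
read_mvarx <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$d
  A <- lapply(seq_len(obj$p), function(i) {
    v <- if (is.matrix(obj$A)) obj$A[i, ] else unlist(obj$A[[i]])
    matrix(v, d, d, byrow = TRUE)
  })
  B <- matrix(obj$B, d, obj$ell + 1L, byrow = TRUE)
  Q <- matrix(obj$Q, d, d, byrow = TRUE)
  mvarx_model(A, B, Q, fs = obj$fs, channel_names = obj$channel_names)
}
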