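#' Stationary second moments of a stable MVAR process
#'
#' For the autoregressive part of a stable model (spectral radius < 1) the
#' spontaneous process is wide-sense stationary with zero mean; its
#' covariance `Sigma = E{y_n y_n'}` solves the discrete-time Lyapunov
#' equation of the companion form (with `Q` embedded in the leading
#' block), and the lagged covariances `Gamma_tau = E{y_{n-tau} y_n'}` are
#' read off the companion solution for `tau < p` and propagated by the
#' Yule-Walker recursion `Gamma_tau = sum_i Gamma_{tau-i} A_i'` beyond.
#' Only `A` and `Q` enter — the stimulus filters `B` describe how input
#' reaches the network, not its internal dynamics.
#'
#' @param model a stable `mvarx_model`.
#' @param rho maximum lag to compute (default `max(p - 1, 30)`).
#' @return object of class `stationary_moments`: `sigma` (`d x d`),
#'   `gamma` (list, `gamma[[tau]]` = lag-`tau` covariance, `tau = 1..rho`),
#'   `rho`.
#' @export
stationary_moments <- function(model, rho = max(model$p - 1, 30)) {
  if (spectral_radius(model) >= 1) stopf("model must be stable (spectral radius < 1)")
  rho <- max(as.integer(rho), model$p - 1L, 1L)
  d <- model$d; p <- model$p
  F <- companion_matrix(model)
  Qc <- matrix(0, d * p, d * p)
  Qc[1:d, 1:d] <- model$Q
  S <- dlyap_doubling(F, Qc)
  # companion stationary covariance: block (i, j) = E{y_{n-i+1} y_{n-j+1}'}
  # so block (tau+1, 1) = E{y_{n-tau} y_n'} = Gamma_tau
  Sigma <- symm(S[1:d, 1:d, drop = FALSE])
  gamma <- vector("list", rho)
  for (tau in seq_len(min(rho, p - 1L)))
    gamma[[tau]] <- S[(tau * d + 1L):((tau + 1L) * d), 1:d, drop = FALSE]
  if (rho >= p) {
    gfull <- c(list(Sigma), gamma)   # gfull[[tau+1]] = Gamma_tau
    for (tau in p:rho) {
      G <- matrix(0, d, d)
      for (i in seq_len(p)) {
        k <- tau - i
        Gk <- if (k >= 0) gfull[[k + 1L]] else t(gfull[[-k + 1L]])
        G <- G + Gk %*% t(model$A[[i]])
      }
      gfull[[tau + 1L]] <- G
      gamma[[tau]] <- G
    }
  }
  structure(list(sigma = Sigma, gamma = gamma, rho = rho, d = d),
            class = "stationary_moments")
}

# discrete Lyapunov solve S = F S F' + Q by doubling:
# S_{k+1} = S_k + F_k S_k F_k', F_{k+1} = F_k^2; geometric convergence for
# spectral radius < 1, avoids the (dp)^2 x (dp)^2 Kronecker system.
dlyap_doubling <- function(F, Q, tol = 1e-14, max_iter = 200L) {
  S <- Q
  Fk <- F
  for (i in seq_len(max_iter)) {
    S <- S + Fk %*% S %*% t(Fk)
    Fk <- Fk %*% Fk
    if (max(abs(Fk)) < tol) break
  }
  symm(S)
}

#' Conditional covariance of the past given the present
#'
#' `Sigma(y_{n-tau} | y_n) = Sigma - Gamma_tau Sigma^{-1} Gamma_tau'` for
#' the full system, or the analogous expression built from the *marginal*
#' blocks `Sigma[s, s]`, `Gamma_tau[s, s]` for a channel subset (the
#' sub-system is the marginal of the full process, not a refitted smaller
#' model).
#'
#' @param moments a [stationary_moments()] object.
#' @param tau lag in samples (`1 <= tau <= rho`).
#' @param subset optional integer vector of channel indices.
#' @return symmetric positive semidefinite covariance matrix.
#' @export
conditional_cov <- function(moments, tau, subset = NULL) {
  if (tau < 1L || tau > moments$rho)
    stopf("`tau` must be in 1..rho = %d", moments$rho)
  s <- subset %||% seq_len(moments$d)
  Sig <- moments$sigma[s, s, drop = FALSE]
  Gam <- moments$gamma[[tau]][s, s, drop = FALSE]
  symm(Sig - Gam %*% solve(Sig, t(Gam)))
}

#' Effective information of a bipartition
#'
#' Kullback-Leibler divergence (in bits) between the system's joint
#' past-given-present distribution and the product of the two parts'
#' marginal past-given-present distributions:
#' \deqn{\varphi(y;\tau,\mathcal{B}) = \tfrac12\big[-\log_2\det\Sigma(y_{n-\tau}|y_n)
#'   + \textstyle\sum_i \log_2\det\Sigma(m^i_{n-\tau}|m^i_n)\big].}
#' Symmetric in the two parts and zero when the parts are dynamically
#' independent (block-diagonal `A` and `Q` aligned with the partition).
#'
#' @param moments a [stationary_moments()] object (or a stable
#'   `mvarx_model`, for which moments are computed).
#' @param tau lag in samples.
#' @param partition list with components `M1`, `M2`: disjoint non-empty
#'   channel index sets covering `1..d`.
#' @return effective information in bits.
#' @export
effective_information <- function(moments, tau, partition) {
  if (inherits(moments, "mvarx_model"))
    moments <- stationary_moments(moments, rho = max(moments$p - 1, tau))
  M1 <- partition$M1; M2 <- partition$M2
  d <- moments$d
  if (length(M1) == 0L || length(M2) == 0L || length(intersect(M1, M2)) ||
      !setequal(c(M1, M2), seq_len(d)))
    stopf("partition must split 1..%d into two disjoint non-empty sets", d)
  ld_full <- log2det(conditional_cov(moments, tau))
  ld1 <- log2det(conditional_cov(moments, tau, M1))
  ld2 <- log2det(conditional_cov(moments, tau, M2))
  if (anyNA(c(ld_full, ld1, ld2)))
    stopf("non-positive conditional covariance determinant (degenerate system)")
  0.5 * (-ld_full + ld1 + ld2)
}

# differential entropy of the marginal Gaussian sub-system, in bits
subsystem_entropy <- function(moments, s) {
  ld <- log2det(moments$sigma[s, s, drop = FALSE])
  if (is.na(ld)) stopf("non-positive determinant of marginal covariance")
  0.5 * (length(s) * log2(2 * pi * exp(1)) + ld)
}

# all canonical bipartitions of 1..d (channel 1 kept in M1)
enumerate_bipartitions <- function(d) {
  out <- vector("list", 2^(d - 1) - 1)
  k <- 0L
  for (code in 1:(2^(d - 1) - 1)) {
    rest <- which(bitwAnd(code, bitwShiftL(1L, 0:(d - 2))) > 0L) + 1L
    k <- k + 1L
    out[[k]] <- list(M1 = c(1L, setdiff(2:d, rest)), M2 = rest)
  }
  out
}

#' Minimum information bipartition and integrated information at one lag
#'
#' Exhaustively searches the `2^(d-1) - 1` canonical bipartitions for the
#' one minimizing the normalized effective information
#' `phi(B) / K2(B)`, where the normalizer `K2(B) = min(H(m1), H(m2))` is
#' the smaller part's differential entropy. Integrated information is the
#' *unnormalized* effective information at that minimum information
#' bipartition (MIB). Partitions whose normalizer is non-positive (possible
#' for low-variance parts, since differential entropy can be negative) are
#' excluded from the argmin with a warning.
#'
#' @param model a stable `mvarx_model` with `d >= 2`.
#' @param tau lag in samples.
#' @param moments optional precomputed [stationary_moments()].
#' @param d_max guard on the exhaustive enumeration (default 20).
#' @return list with `mib` (the partition), `phi` (bits), and `table`
#'   (per-partition phi, normalizer and normalized score).
#' @export
minimum_information_bipartition <- function(model, tau, moments = NULL,
                                            d_max = 20) {
  d <- model$d
  if (d < 2L) stopf("need d >= 2 channels to bipartition")
  if (d > d_max) stopf("d = %d exceeds enumeration guard d_max = %d", d, d_max)
  moments <- moments %||% stationary_moments(model, rho = max(model$p - 1, tau))
  parts <- enumerate_bipartitions(d)
  n <- length(parts)
  phi <- numeric(n); K2 <- numeric(n)
  lab <- character(n)
  for (i in seq_len(n)) {
    phi[i] <- effective_information(moments, tau, parts[[i]])
    K2[i] <- min(subsystem_entropy(moments, parts[[i]]$M1),
                 subsystem_entropy(moments, parts[[i]]$M2))
    lab[i] <- paste0("{", paste(parts[[i]]$M1, collapse = ","), "}|{",
                     paste(parts[[i]]$M2, collapse = ","), "}")
  }
  ok <- K2 > 0
  if (!any(ok)) stopf("all bipartition normalizers are non-positive")
  if (!all(ok))
    warning(sprintf("%d bipartition(s) excluded: non-positive entropy normalizer",
                    sum(!ok)))
  score <- ifelse(ok, phi / K2, Inf)
  best <- which.min(score)
  list(mib = parts[[best]], phi = phi[best],
       table = data.frame(partition = lab, phi = phi, K2 = K2,
                          score = ifelse(ok, phi / K2, NA_real_)))
}

#' Integrated information profile over a lag grid
#'
#' Computes the MIB and integrated information `phi(tau)` for every lag in
#' the grid (default 1..30 samples, i.e. 10-300 ms at 100 Hz) and records
#' the maximum and its lag — the lag of peak integration is itself
#' informative (longer in sleep than wakefulness).
#'
#' @param model a stable `mvarx_model`, `d >= 2`.
#' @param tau_grid strictly increasing lags in samples (default 1:30).
#' @return object of class `phi_profile` with `taus`, `tau_ms`, `phi`,
#'   `mib` (list of partitions), `phi_max`, `tau_argmax`.
#' @export
phi_profile <- function(model, tau_grid = 1:30) {
  tau_grid <- as.integer(tau_grid)
  if (any(tau_grid < 1L) || is.unsorted(tau_grid, strictly = TRUE))
    stopf("`tau_grid` must be strictly increasing lags >= 1")
  moments <- stationary_moments(model, rho = max(model$p - 1, max(tau_grid)))
  phi <- numeric(length(tau_grid))
  mib <- vector("list", length(tau_grid))
  for (k in seq_along(tau_grid)) {
    res <- minimum_information_bipartition(model, tau_grid[k], moments = moments)
    phi[k] <- res$phi; mib[[k]] <- res$mib
  }
  imax <- which.max(phi)
  structure(list(taus = tau_grid, tau_ms = 1000 * tau_grid / model$fs,
                 phi = phi, mib = mib, phi_max = phi[imax],
                 tau_argmax = tau_grid[imax], fs = model$fs),
            class = "phi_profile")
}

#' @export
print.phi_profile <- function(x, ...) {
  cat(sprintf("phi_profile: %d lags (%g-%g ms); phi_max = %.4f bits at tau = %d samples (%g ms)\n",
              length(x$taus), min(x$tau_ms), max(x$tau_ms), x$phi_max,
              x$tau_argmax, 1000 * x$tau_argmax / x$fs))
  invisible(x)
}

#' Compare integrated information between two conditions
#'
#' Two-sided Wilcoxon rank-sum test for equal medians of per-CV-partition
#' maximum integrated information in two conditions (e.g. wakefulness vs
#' NREM sleep). Exact for small tie-free samples.
#'
#' @param phi_max_a,phi_max_b numeric vectors of per-partition maxima
#'   (each length >= 2).
#' @return two-sided p-value.
#' @export
compare_conditions <- function(phi_max_a, phi_max_b) {
  if (length(phi_max_a) < 2L || length(phi_max_b) < 2L)
    stopf("need at least 2 values per condition")
  suppressWarnings(
    stats::wilcox.test(phi_max_a, phi_max_b, alternative = "two.sided",
                       correct = FALSE)$p.value)
}
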