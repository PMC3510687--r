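test_that("stationary moments match scalar AR(1) closed forms exactly", {
  a <- 0.9; q <- 2
  m <- mvarx_model(matrix(a), matrix(0), matrix(q))
  mo <- stationary_moments(m, 10)
  S <- q / (1 - a^2)
  expect_equal(mo$sigma[1, 1], S, tolerance = 1e-12)
  for (tau in c(1, 3, 10))
    expect_equal(mo$gamma[[tau]][1, 1], a^tau * S, tolerance = 1e-12)
  # conditional variance Sigma * (1 - a^(2 tau))
  for (tau in c(1, 4))
    expect_equal(conditional_cov(mo, tau)[1, 1], S * (1 - a^(2 * tau)),
                 tolerance = 1e-12)
  expect_error(stationary_moments(mvarx_model(matrix(1.01), matrix(0),
                                              matrix(1))), "stable")
})

test_that("block-diagonal systems give block-diagonal moments", {
  m <- block_model()
  mo <- stationary_moments(m, 5)
  off <- rbind(cbind(matrix(0, 2, 2), matrix(1, 2, 2)),
               cbind(matrix(1, 2, 2), matrix(0, 2, 2)))
  expect_equal(max(abs(mo$sigma * off)), 0)
  for (tau in 1:5) expect_equal(max(abs(mo$gamma[[tau]] * off)), 0)
})

test_that("moments agree with an empirical long simulation", {
  m <- random_stable_mvarx(3, 2, 0, 0.85, seed = 80, b_scale = 0)
  tr0 <- stim_train(n_pulses = 1, pulse_waveform = 0)
  s <- simulate_session(m, tr0, 2e5, seed = 81)
  mo <- stationary_moments(m, 3)
  emp0 <- tcrossprod(s$y) / ncol(s$y)
  expect_lt(rel_frob(emp0, mo$sigma), 0.05)
  emp2 <- tcrossprod(s$y[, 1:(2e5 - 2)], s$y[, 3:2e5]) / (2e5 - 2)
  expect_lt(norm(emp2 - mo$gamma[[2]], "F") / norm(mo$sigma, "F"), 0.05)
})

test_that("conditional covariance contracts the generalized variance", {
  m <- random_stable_mvarx(4, 2, 0, 0.8, seed = 82, b_scale = 0)
  mo <- stationary_moments(m, 8)
  for (tau in c(1, 8)) {
    cc <- conditional_cov(mo, tau)
    expect_true(all(eigen(cc, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
    expect_lte(det(cc), det(mo$sigma) * (1 + 1e-12))
  }
  # A = 0: past independent of present, conditional equals marginal
  m0 <- mvarx_model(matrix(0, 3, 3), matrix(0, 3, 1), diag(3) + 0.2)
  mo0 <- stationary_moments(m0, 2)
  expect_equal(conditional_cov(mo0, 1), mo0$sigma, tolerance = 1e-12)
})

test_that("effective information matches an independent 2-channel oracle", {
  # coupled 2-channel VAR(1); oracle assembles everything from the
  # Kronecker-solved Lyapunov equation, independent of the package path
  A <- matrix(c(0.5, 0.3, 0.2, 0.4), 2, 2)
  Q <- matrix(c(1, 0.1, 0.1, 0.8), 2, 2)
  m <- mvarx_model(A, matrix(0, 2, 1), Q)
  Sig <- matrix(solve(diag(4) - kronecker(A, A), as.vector(Q)), 2, 2)
  tau <- 3
  Gam <- Sig
  for (k in 1:tau) Gam <- Gam %*% t(A)           # Gamma_tau = Sigma (A')^tau
  cc_full <- Sig - Gam %*% solve(Sig) %*% t(Gam)
  ld <- function(M) log2(det(M))
  cond1 <- function(i) Sig[i, i] - Gam[i, i]^2 / Sig[i, i]
  phi_oracle <- 0.5 * (-ld(cc_full) + log2(cond1(1)) + log2(cond1(2)))
  expect_equal(effective_information(m, tau, list(M1 = 1L, M2 = 2L)),
               phi_oracle, tolerance = 1e-10)
  expect_gt(phi_oracle, 0)
  # symmetric under swapping the parts
  expect_equal(effective_information(m, tau, list(M1 = 2L, M2 = 1L)),
               effective_information(m, tau, list(M1 = 1L, M2 = 2L)))
})

test_that("phi vanishes for dynamically independent partitions", {
  m <- block_model()
  expect_equal(effective_information(m, 1, list(M1 = c(1, 2), M2 = c(3, 4))), 0,
               tolerance = 1e-10)
  # no temporal structure at all: any partition gives zero
  m0 <- mvarx_model(matrix(0, 4, 4), matrix(0, 4, 1), diag(c(1, 2, 3, 4)))
  expect_equal(effective_information(m0, 1, list(M1 = c(1, 3), M2 = c(2, 4))), 0,
               tolerance = 1e-12)
})

test_that("MIB search equals a brute-force re-enumeration", {
  m <- random_stable_mvarx(4, 2, 0, 0.85, seed = 83, b_scale = 0)
  tau <- 2
  res <- minimum_information_bipartition(m, tau)
  # independent enumeration: all 7 canonical bipartitions by hand
  mo <- stationary_moments(m, tau)
  subsets <- list(1L, 2L, 3L, 4L, c(1L, 2L), c(1L, 3L), c(1L, 4L))
  H <- function(s) 0.5 * log2((2 * pi * exp(1))^length(s) *
                                det(mo$sigma[s, s, drop = FALSE]))
  phi_of <- function(s1) {
    s2 <- setdiff(1:4, s1)
    cc <- function(s) {
      Si <- mo$sigma[s, s, drop = FALSE]; G <- mo$gamma[[tau]][s, s, drop = FALSE]
      Si - G %*% solve(Si) %*% t(G)
    }
    0.5 * (-log2(det(cc(1:4))) + log2(det(cc(s1))) + log2(det(cc(s2))))
  }
  scores <- vapply(subsets, function(s1)
    phi_of(s1) / min(H(s1), H(setdiff(1:4, s1))), numeric(1))
  best <- subsets[[which.min(scores)]]
  expect_setequal(res$mib$M1, if (1 %in% best) best else setdiff(1:4, best))
  expect_equal(res$phi, phi_of(best), tolerance = 1e-10)
  expect_equal(nrow(res$table), 7)

  # block-independent system: MIB is the aligned cut with phi = 0
  rb <- minimum_information_bipartition(block_model(), 1)
  expect_setequal(rb$mib$M1, c(1, 2))
  expect_equal(rb$phi, 0, tolerance = 1e-10)

  # d = 2: single candidate
  m2 <- mvarx_model(matrix(c(0.5, 0.2, 0.1, 0.3), 2), matrix(0, 2, 1), diag(2))
  r2 <- minimum_information_bipartition(m2, 1)
  expect_setequal(r2$mib$M1, 1)
  expect_error(minimum_information_bipartition(
    mvarx_model(matrix(0.5), matrix(0), matrix(1)), 1), "d >= 2")
})

test_that("phi_profile records the maximum and respects grid refinement", {
  # A = 0: flat zero profile
  m0 <- mvarx_model(matrix(0, 3, 3), matrix(0, 3, 1), diag(3))
  pr0 <- phi_profile(m0, 1:10)
  expect_equal(pr0$phi, rep(0, 10), tolerance = 1e-10)

  m <- random_stable_mvarx(4, 2, 0, 0.9, seed = 84, b_scale = 0)
  pr <- phi_profile(m, c(1, 5, 10, 20))
  expect_true(all(is.finite(pr$phi)))
  expect_equal(pr$phi_max, max(pr$phi))
  expect_equal(pr$tau_ms, c(10, 50, 100, 200))
  # a superset grid can only raise the maximum
  pr2 <- phi_profile(m, c(1:10, 20))
  expect_gte(pr2$phi_max, pr$phi_max - 1e-12)

  expect_error(phi_profile(m, c(3, 2)), "increasing")
})

test_that("phi is invariant under channel permutation of the partition", {
  m <- random_stable_mvarx(5, 2, 0, 0.8, seed = 85, b_scale = 0)
  perm <- c(4, 2, 5, 1, 3)
  mp <- mvarx_model(lapply(m$A, function(Ai) Ai[perm, perm]),
                    m$B[perm, , drop = FALSE], m$Q[perm, perm])
  part <- list(M1 = c(1L, 3L), M2 = c(2L, 4L, 5L))
  ppart <- list(M1 = match(part$M1, perm), M2 = match(part$M2, perm))
  expect_equal(effective_information(mp, 2, ppart),
               effective_information(m, 2, part), tolerance = 1e-10)
})

test_that("phi at the block cut shrinks continuously with the coupling", {
  phis <- vapply(c(0.3, 0.1, 0.03, 0), function(cpl) {
    A <- matrix(0, 4, 4)
    A[1:2, 1:2] <- matrix(c(0.5, 0.2, -0.1, 0.4), 2)
    A[3:4, 3:4] <- matrix(c(0.3, 0.1, 0.2, 0.5), 2)
    A[1, 3] <- A[3, 1] <- cpl
    effective_information(mvarx_model(A, matrix(0, 4, 1), diag(4)), 1,
                          list(M1 = c(1, 2), M2 = c(3, 4)))
  }, numeric(1))
  expect_true(all(diff(phis) < 1e-12))
  expect_equal(phis[4], 0, tolerance = 1e-12)
})

test_that("compare_conditions is a two-sided rank-sum test", {
  expect_equal(compare_conditions(c(1, 2, 3), c(1, 2, 3)), 1)
  # full separation at n = m = 7: exact two-sided tail 2 / choose(14, 7)
  a <- 1:7; b <- 8:14
  expect_equal(compare_conditions(a, b), 2 / choose(14, 7), tolerance = 1e-12)
  expect_equal(compare_conditions(b, a), compare_conditions(a, b))
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})
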