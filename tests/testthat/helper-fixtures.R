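# shared fixtures, all generated in code at test time

theta_of <- function(m) cbind(do.call(cbind, m$A), m$B)

rel_frob <- function(a, b) norm(a - b, "F") / norm(b, "F")

# default-protocol session from a seeded random system
default_session <- function(d = 4, p = 3, ell = 10, radius = 0.8,
                            seed = 1, n_samples = 3012, ...) {
  m <- random_stable_mvarx(d, p, ell, radius, seed = seed, ...)
  simulate_session(m, stim_train(), n_samples, seed = seed + 5000)
}

# epochs of pure N(0, I) noise, no input
gaussian_epochs <- function(J = 30, d = 4, N = 100, seed = 1) {
  set.seed(seed)
  epoch_set(lapply(seq_len(J), function(j) matrix(rnorm(d * N), d, N)),
            lapply(seq_len(J), function(j) numeric(N)))
}

# strongly coupled "wake-like" system: dense A, fast dynamics
wake_model <- function(seed = 11) random_stable_mvarx(6, 2, 10, 0.85, seed = seed)

# "sleep-like" system: two 3-channel blocks with strong intra-block and
# weak (5%) inter-block coupling, slower dynamics (radius 0.92).
# By construction integrated information is low; the wake/sleep direction
# of the contrast is a property of this fixture.
sleep_model <- function(seed = 12) {
  set.seed(seed)
  blk <- function() matrix(rnorm(9), 3, 3)
  A1 <- matrix(0, 6, 6); A1[1:3, 1:3] <- blk(); A1[4:6, 4:6] <- blk()
  A2 <- matrix(0, 6, 6); A2[1:3, 1:3] <- 0.5 * blk(); A2[4:6, 4:6] <- 0.5 * blk()
  A1[1:3, 4:6] <- 0.05 * blk(); A1[4:6, 1:3] <- 0.05 * blk()
  A <- list(A1, A2)
  rho <- max(Mod(eigen(companion_matrix(A), only.values = TRUE)$values))
  A <- lapply(seq_along(A), function(i) A[[i]] * (0.92 / rho)^i)
  mvarx_model(A, matrix(rnorm(66, sd = 20), 6, 11), diag(6) + 0.05, fs = 100)
}

# block-independent 4-channel system (2+2), for phi = 0 checks
block_model <- function() {
  A1 <- matrix(0, 4, 4)
  A1[1:2, 1:2] <- matrix(c(0.5, 0.2, -0.1, 0.4), 2)
  A1[3:4, 3:4] <- matrix(c(0.3, 0.1, 0.2, 0.5), 2)
  Q <- diag(4); Q[1, 2] <- Q[2, 1] <- 0.3; Q[3, 4] <- Q[4, 3] <- -0.2
  mvarx_model(A1, matrix(0, 4, 1), Q, fs = 100)
}

# order-5 system with genuinely strong lag-5 dynamics (order recovery)
lag5_model <- function(seed) {
  set.seed(seed)
  A <- list(0.3 * matrix(rnorm(16), 4, 4), matrix(0, 4, 4), matrix(0, 4, 4),
            matrix(0, 4, 4), matrix(rnorm(16), 4, 4))
  rho <- max(Mod(eigen(companion_matrix(A), only.values = TRUE)$values))
  A <- lapply(seq_along(A), function(i) A[[i]] * (0.9 / rho)^i)
  W <- matrix(rnorm(16), 4, 4)
  mvarx_model(A, matrix(rnorm(44, sd = 20), 4, 11), W %*% t(W) + 0.1 * diag(4),
              fs = 100)
}

# fit a 5000-sample default-protocol session as one contiguous segment and
# return the corrected whiteness statistic (t2 replicate)
whiteness_T_replicate <- function(seed) {
  m <- random_stable_mvarx(4, 3, 10, 0.8, seed = seed)
  s <- simulate_session(m, stim_train(), 5000, seed = seed + 20000L)
  f <- mvarx_fit(epoch_set(list(s$y), list(s$x), fs = 100), 3, 10)
  whiteness_test(mvarx_residuals(f), alpha = 0.1, fit = f)$T
}
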