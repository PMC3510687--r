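test_that("build_regression lays out the regressor exactly as specified", {
  # d = 1, p = 1, ell = 0: epoch [y1 y2 y3], input [x1 x2 x3]
  y <- matrix(c(2, 5, 11), 1, 3)
  x <- c(0.5, 1, 7)
  ep <- epoch_set(list(y), list(x))
  reg <- build_regression(ep, 1, 0)
  expect_equal(reg$n0, 1)
  expect_equal(reg$Y[[1]], matrix(c(5, 11), 1, 2))
  expect_equal(reg$Z[[1]], matrix(c(2, 1, 5, 7), 2, 2))  # cols [y1,x2],[y2,x3]

  # regressor row count d*p + ell + 1; column count sum(Nj - n0)
  ep2 <- epoch_set(list(matrix(rnorm(3 * 40), 3, 40), matrix(rnorm(3 * 25), 3, 25)),
                   list(rnorm(40), rnorm(25)))
  reg2 <- build_regression(ep2, 4, 6)
  expect_equal(nrow(reg2$Z[[1]]), 3 * 4 + 6 + 1)
  expect_equal(sum(vapply(reg2$Z, ncol, integer(1))), (40 - 6) + (25 - 6))
  expect_equal(reg2$Nt, 65 - 6 * 2)

  # x enters at lag 0: top x-row of Z equals x_n
  expect_equal(reg2$Z[[1]][13, ], ep2$inputs[[1]][7:40])

  expect_error(build_regression(ep2, 4, 30), "shorter than")
})

test_that("OLS recovers the generating model from noiseless data exactly", {
  m <- random_stable_mvarx(4, 3, 10, 0.9, seed = 1)
  m0 <- mvarx_model(m$A, m$B, matrix(0, 4, 4), fs = 100)
  s <- simulate_session(m0, stim_train(), 3012, seed = 2)
  f <- mvarx_fit(segment_epochs(s), 3, 10)
  expect_lt(rel_frob(theta_of(f), theta_of(m)), 1e-9)
  expect_lt(max(abs(f$Q)), 1e-18)
})

test_that("OLS residuals satisfy the normal equations and match one-step residuals", {
  s <- default_session(seed = 50)
  ep <- segment_epochs(s)
  f <- mvarx_fit(ep, 3, 10)
  reg <- build_regression(ep, 3, 10)
  R <- do.call(cbind, mvarx_residuals(f))
  Z <- do.call(cbind, reg$Z)
  expect_lt(norm(R %*% t(Z), "F") / norm(do.call(cbind, reg$Y) %*% t(Z), "F"), 1e-10)
  # one_step_predict with the fitted model reproduces the OLS residuals
  osp <- one_step_predict(f, ep)
  expect_equal(osp$residuals, mvarx_residuals(f), tolerance = 1e-12)
  # Q-hat equals residual cross-product over Nt
  expect_equal(f$Q, tcrossprod(R) / reg$Nt, tolerance = 1e-12)
})

test_that("rank-deficient regressors raise an informative error", {
  # constant-zero channel makes lagged regressors collinear
  ep <- epoch_set(list(rbind(numeric(60), rnorm(60))), list(numeric(60)))
  expect_error(mvarx_fit(ep, 2, 3), "rank deficient")
})

test_that("one-step prediction handles the zero model and held-out data", {
  s <- default_session(seed = 51)
  ep <- segment_epochs(s)
  zero <- mvarx_model(replicate(3, matrix(0, 4, 4), simplify = FALSE),
                      matrix(0, 4, 11), diag(4))
  osp <- one_step_predict(zero, ep)
  expect_true(all(vapply(osp$predictions, function(P) all(P == 0), logical(1))))
  expect_equal(osp$residuals[[5]], ep$epochs[[5]][, 11:100])

  # with the true model on held-out data, mean squared residual ~ tr(Q)
  m <- s$truth$model
  s2 <- simulate_session(m, stim_train(), 3012, seed = 52)
  osp2 <- one_step_predict(m, segment_epochs(s2))
  msr <- mean(vapply(osp2$residuals, function(E) mean(colSums(E^2)), numeric(1)))
  expect_lt(abs(msr - sum(diag(m$Q))) / sum(diag(m$Q)), 0.1)
})

test_that("simulate_evoked is linear and purely input-driven", {
  m <- random_stable_mvarx(3, 2, 5, 0.8, seed = 6)
  expect_equal(simulate_evoked(m, numeric(300)), matrix(0, 3, 300))
  # superposition of well-separated pulses
  x1 <- numeric(400); x1[50] <- 1
  x2 <- numeric(400); x2[250] <- 1
  expect_equal(simulate_evoked(m, x1 + x2),
               simulate_evoked(m, x1) + simulate_evoked(m, x2),
               tolerance = 1e-12)
})

test_that("spectral_radius matches companion eigenvalues", {
  expect_equal(spectral_radius(mvarx_model(matrix(0, 2, 2), matrix(0, 2, 1),
                                           diag(2))), 0)
  expect_equal(spectral_radius(mvarx_model(matrix(0.9), matrix(0), matrix(1))), 0.9)
  # d=1, p=2, a1 = a2 = 0.5: largest root of z^2 - 0.5z - 0.5 is exactly 1
  m2 <- mvarx_model(list(matrix(0.5), matrix(0.5)), matrix(0), matrix(1))
  expect_equal(spectral_radius(m2), 1, tolerance = 1e-12)
})

test_that("estimation is equivariant under channel permutation", {
  s <- default_session(seed = 53)
  ep <- segment_epochs(s)
  f <- mvarx_fit(ep, 2, 5)
  perm <- c(3, 1, 4, 2)
  epp <- epoch_set(lapply(ep$epochs, function(e) e[perm, , drop = FALSE]),
                   ep$inputs, x_full = ep$x_full, starts = ep$starts)
  fp <- mvarx_fit(epp, 2, 5)
  for (i in 1:2) expect_equal(fp$A[[i]], f$A[[i]][perm, perm], tolerance = 1e-9)
  expect_equal(fp$B, f$B[perm, ], tolerance = 1e-9)
  expect_equal(fp$Q, f$Q[perm, perm], tolerance = 1e-9)
})

test_that("Q-hat is consistent at large sample size", {
  m <- random_stable_mvarx(3, 2, 4, 0.8, seed = 54)
  tr <- stim_train(n_pulses = 100, isi = 1000)
  s <- simulate_session(m, tr, 1e5 + 12, seed = 55)
  f <- mvarx_fit(epoch_set(list(s$y), list(s$x), fs = 100), 2, 4)
  expect_lt(rel_frob(f$Q, m$Q), 0.05)
})

test_that("decompose splits a no-input session trivially", {
  m <- random_stable_mvarx(3, 2, 4, 0.8, seed = 56)
  tr0 <- stim_train(n_pulses = 1, pulse_waveform = 0)
  s <- simulate_session(m, tr0, 500, seed = 57)
  dec <- mvarx_decompose(m, s)
  expect_equal(dec$spontaneous, s$y)
  expect_equal(dec$evoked, matrix(0, 3, 500))
})

test_that("model JSON serialization round-trips losslessly", {
  m <- random_stable_mvarx(5, 4, 7, 0.85, seed = 58)
  path <- tempfile(fileext = ".json")
  write_mvarx(m, path)
  m2 <- read_mvarx(path)
  expect_equal(m2$A, m$A, tolerance = 0)
  expect_equal(m2$B, m$B, tolerance = 0)
  expect_equal(m2$Q, m$Q, tolerance = 0)
  expect_identical(m2$channel_names, m$channel_names)
  expect_equal(m2$fs, m$fs)
  unlink(path)
})
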