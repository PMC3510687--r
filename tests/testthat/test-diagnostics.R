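test_that("bartlett_window and kernel_width follow their formulas", {
  expect_equal(bartlett_window(2), c(1, 0.5, 0))
  expect_equal(bartlett_window(5)[1], 1)
  expect_equal(bartlett_window(5)[6], 0)
  expect_error(bartlett_window(0), "`L`")

  expect_equal(kernel_width(3000), 34L)
  expect_equal(kernel_width(1), 3L)
  expect_equal(kernel_width(100), as.integer(ceiling(3 * 100^0.3)))  # 12
})

test_that("residual_autocov estimates lagged covariances correctly", {
  set.seed(1)
  W <- matrix(rnorm(3 * 4000), 3, 4000)
  # single epoch, r = 0: ordinary sample covariance with Nc = N1
  C0 <- residual_autocov(W, 0, 30)
  expect_equal(C0, tcrossprod(W) / 4000)
  expect_equal(C0, t(C0))

  # AR(1) residuals: C(1) ~ a * C(0)
  a <- 0.7
  ar <- matrix(as.numeric(stats::filter(rnorm(6000), a, "recursive")), 1)
  C0a <- residual_autocov(ar, 0, 20)[1, 1]
  C1a <- residual_autocov(ar, 1, 20)[1, 1]
  expect_equal(C1a / C0a, a, tolerance = 0.05)

  # multi-epoch: only within-epoch pairs contribute
  Wl <- list(W[, 1:2000], W[, 2001:4000])
  L <- 10
  C1l <- residual_autocov(Wl, 1, L)
  manual <- (tcrossprod(Wl[[1]][, 1:1999], Wl[[1]][, 2:2000]) +
             tcrossprod(Wl[[2]][, 1:1999], Wl[[2]][, 2:2000])) / (4000 - L)
  expect_equal(C1l, manual)

  expect_error(residual_autocov(lapply(1:5, function(i) W[, 1:50]), 1, 20),
               "must exceed")
})

test_that("whiteness_test is calibrated on white noise and powerful against AR(1)", {
  # null calibration on raw i.i.d. residuals (no fitting): modest replicate
  # count here; the full 500-replicate calibration lives in the acceptance suite
  Ts <- vapply(1:60, function(i) {
    set.seed(i)
    whiteness_test(matrix(rnorm(3 * 3000), 3, 3000))$T
  }, numeric(1))
  expect_lt(abs(mean(Ts)), 0.45)
  expect_gt(var(Ts), 0.5); expect_lt(var(Ts), 2)

  # strongly autocorrelated residuals are rejected
  set.seed(2)
  ar <- matrix(as.numeric(stats::filter(rnorm(3000), 0.8, "recursive")), 1)
  wt <- whiteness_test(ar)
  expect_true(wt$reject)
  expect_gt(wt$T, 10)

  # L resolution: single epoch of 3000 -> the documented L = 34
  wt2 <- whiteness_test(matrix(rnorm(2 * 3000), 2, 3000))
  expect_equal(wt2$L, 34L)
  expect_equal(wt2$Nc, 3000L)

  # channel permutation leaves the statistic unchanged
  set.seed(3)
  W <- matrix(rnorm(4 * 2000), 4, 2000)
  expect_equal(whiteness_test(W[c(3, 1, 4, 2), ])$T, whiteness_test(W)$T)
})

test_that("correctly specified MVARX fits pass, unconnected ARX fits fail", {
  rej_full <- logical(4); rej_unc <- logical(4)
  for (i in 1:4) {
    m <- random_stable_mvarx(4, 3, 10, 0.8, seed = 150 + i)
    s <- simulate_session(m, stim_train(), 5000, seed = 160 + i)
    ep <- epoch_set(list(s$y), list(s$x), fs = 100)
    f <- mvarx_fit(ep, 3, 10)
    rej_full[i] <- whiteness_test(mvarx_residuals(f), fit = f)$reject
    fu <- fit_unconnected(ep, 3, 10)
    rej_unc[i] <- whiteness_test(mvarx_residuals(fu))$reject
  }
  expect_lte(sum(rej_full), 1)     # ~ alpha-level false alarms at most
  expect_equal(sum(rej_unc), 4)    # coupling ignored -> serial correlation
})

test_that("average_cv_responses obeys its averaging identities", {
  s <- default_session(seed = 70)
  ep <- segment_epochs(s)
  part <- partition_cv(30, 10)     # equal test sizes
  models <- lapply(part$train, function(tr) mvarx_fit(subset_epochs(ep, tr), 2, 5))
  avg <- average_cv_responses(ep, models, part)
  expect_equal(dim(avg$measured), c(4, 100))
  # equal-size test sets: two-phase measured average equals pooled average
  pooled <- Reduce(`+`, ep$epochs) / 30
  expect_equal(avg$measured, pooled, tolerance = 1e-12)

  # M = 1 reduces to plain test-set averages
  p1 <- partition_cv(30, 2)
  m1 <- mvarx_fit(subset_epochs(ep, p1$train[[1]]), 2, 5)
  one <- structure(list(test = p1$test[1], train = p1$train[1], J = 30L, M = 1L),
                   class = "cv_partition")
  avg1 <- average_cv_responses(ep, list(m1), one)
  expect_equal(avg1$measured, Reduce(`+`, ep$epochs[p1$test[[1]]]) /
                 length(p1$test[[1]]))

  expect_error(average_cv_responses(ep, models[1:3], part), "one model per")
})

test_that("fit metrics match their definitions and invariances", {
  set.seed(4)
  meas <- matrix(rnorm(4 * 100), 4, 100)
  # identical traces: zero NMSD / NMRD, RRMS max is 1
  fm0 <- fit_metrics(meas, meas)
  expect_equal(fm0$nmsd, rep(0, 4))
  expect_equal(fm0$nmrd, 0)
  expect_equal(max(fm0$rrms), 1)

  modl <- meas + 0.1 * matrix(rnorm(400), 4, 100)
  fm <- fit_metrics(meas, modl)
  expect_equal(fm$nmsd, rowSums((meas - modl)^2) / rowSums(meas^2))
  expect_equal(fm$nmrd, sum((meas - modl)^2) / sum(meas^2))

  # duplicated channel shares NMSD and RRMS
  fm2 <- fit_metrics(meas[c(1, 1, 2), ], modl[c(1, 1, 2), ])
  expect_equal(fm2$nmsd[1], fm2$nmsd[2])
  expect_equal(fm2$rrms[1], fm2$rrms[2])

  # common positive rescaling changes nothing
  fm3 <- fit_metrics(3 * meas, 3 * modl)
  expect_equal(fm3$nmsd, fm$nmsd)
  expect_equal(fm3$rrms, fm$rrms)
  expect_equal(fm3$nmrd, fm$nmrd)

  expect_error(fit_metrics(matrix(0, 2, 10), matrix(1, 2, 10)), "all-zero")
})

test_that("NMSE uses the n0-trimmed numerator over the full-sample denominator", {
  s <- default_session(seed = 71)
  ep <- segment_epochs(s)
  zero <- mvarx_model(replicate(3, matrix(0, 4, 4), simplify = FALSE),
                      matrix(0, 4, 11), diag(4))
  meas <- Reduce(`+`, ep$epochs) / 30
  fm <- fit_metrics(meas, 0 * meas + 1e-6, zero, ep)
  num <- sum(vapply(ep$epochs, function(Y) sum(Y[, 11:100]^2), numeric(1))) / (30 * 90)
  den <- sum(vapply(ep$epochs, function(Y) sum(Y^2), numeric(1))) / (30 * 100)
  expect_equal(fm$nmse, num / den, tolerance = 1e-12)
})
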