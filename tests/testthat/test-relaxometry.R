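test_that("baseline estimation is the mean of the baseline window", {
  expect_equal(estimate_baseline(rep(500, 20), 10), 500)
  expect_error(estimate_baseline(c(400, 600), 2), "n_baseline")
  sim <- simulate_voxel(healthy_truth(), default_acq())
  expect_equal(estimate_baseline(sim$signal_ge, 10), 1000)
})

test_that("delta-R conversion inverts the signal model exactly", {
  expect_equal(as.numeric(compute_delta_r(rep(1000, 5), 1000, 0.09)),
               rep(0, 5))
  expect_equal(as.numeric(compute_delta_r(1000 * exp(-0.9), 1000, 0.09)),
               10)
  # linearity: any sampled non-negative curve is recovered exactly
  set.seed(1)
  for (rep in 1:5) {
    c_t <- abs(rnorm(60, sd = 10))
    s <- 1234 * exp(-0.022 * c_t)
    expect_equal(as.numeric(compute_delta_r(s, 1234, 0.022)), c_t,
                 tolerance = 1e-12)
  }
})

test_that("non-positive signal frames invalidate the voxel", {
  s <- c(rep(100, 10), -1, rep(100, 9))
  out <- compute_delta_r(s, 100, 0.09)
  expect_false(attr(out, "valid"))
  expect_true(all(is.na(out)))
  expect_error(compute_delta_r(rep(10, 5), 0, 0.09), "S0")
  expect_error(compute_delta_r(rep(10, 5), 100, 0), "TE")
})

test_that("leakage correction recovers planted K1 and K2", {
  acq <- default_acq()
  ref <- gamma_variate(acq$time, 1.2, 15, 3, 2)
  # a voxel whose intravascular curve equals the reference makes the
  # two-parameter leakage model exact, so least squares must recover K
  cum <- pracma::cumtrapz(acq$time, ref)[, 1]
  measured <- 1 * ref - 0.02 * cum
  lk <- leakage_correct(measured, ref, acq$time)
  expect_lt(abs(lk$k2 - 0.02), 1e-6)
  expect_lt(abs(lk$k1 - 1), 1e-6)
  # corrected tail reverts toward baseline
  expect_lt(mean(abs(tail(lk$corrected, 5))),
            mean(abs(tail(measured, 5))))
  # idempotence: re-correcting gives K2 ~ 0
  lk2 <- leakage_correct(lk$corrected, ref, acq$time)
  expect_lt(abs(lk2$k2), 1e-8)
})

test_that("leakage correction is a near no-op for non-leaky voxels", {
  acq <- default_acq()
  ref <- gamma_variate(acq$time, 1.2, 15, 3, 2)
  curve <- 0.8 * ref
  lk <- leakage_correct(curve, ref, acq$time)
  expect_lt(abs(lk$k2), 1e-10)
  expect_equal(lk$corrected, curve, tolerance = 1e-9)
  expect_error(leakage_correct(curve, rep(0, 60), acq$time),
               "degenerate")
})

test_that("gamma-variate fit recovers noiseless parameters", {
  acq <- default_acq()
  curve <- gamma_variate(acq$time, 20, 15, 3, 2)
  fit <- fit_gamma_variate(curve, acq$time)
  expect_true(fit$valid)
  expect_lt(abs(fit$ttp - 21), 0.01)
  expect_equal(fit$alpha, 3, tolerance = 1e-3)
  expect_equal(fit$beta, 2, tolerance = 1e-3)
  expect_gt(fit$r2, 0.9999)
  # ttp identity holds to numerical precision
  expect_lt(abs(fit$ttp - (fit$t0 + fit$alpha * fit$beta)), 1e-9)
})

test_that("flat and noise-only curves are flagged invalid", {
  acq <- default_acq()
  expect_false(fit_gamma_variate(rep(0, 60), acq$time)$valid)
  set.seed(9)
  expect_false(fit_gamma_variate(rnorm(60, sd = 0.5), acq$time)$valid)
})

test_that("fitted ttp is near the information bound at peak SNR 20", {
  # at TR = 1.5 s, 60 frames and peak SNR 20 the Cramer-Rao bound for
  # the time-to-peak of this curve is sigma ~ 0.19 s; the nonlinear
  # least-squares fit should be close to efficient and unbiased
  acq <- default_acq()
  true_curve <- gamma_variate(acq$time, 20, 15, 3, 2)
  peak <- max(true_curve)
  set.seed(314)
  errs <- replicate(200, {
    fit <- fit_gamma_variate(true_curve + rnorm(60, sd = peak / 20),
                             acq$time)
    expect_true(fit$valid)
    fit$ttp - 21
  })
  expect_lt(sd(errs), 1.25 * 0.189)
  expect_lt(abs(mean(errs)), 0.05)
  expect_gte(mean(abs(errs) <= 0.45), 0.95)
})

test_that("batch fitter matches the single-voxel reference fit", {
  acq <- default_acq()
  set.seed(21)
  curves <- sapply(1:12, function(i) {
    amp <- runif(1, 2, 30)
    gamma_variate(acq$time, amp, runif(1, 13, 16), runif(1, 2, 5),
                  runif(1, 1, 3)) + rnorm(60, sd = amp / 60)
  })
  bf <- vamkit:::fit_gamma_batch(curves, acq$time, 10)
  for (i in 1:12) {
    sf <- fit_gamma_variate(curves[, i], acq$time)
    expect_equal(bf$ttp[i], sf$ttp, tolerance = 1e-3)
    expect_equal(bf$peak[i], sf$peak, tolerance = 1e-3)
  }
})
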