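test_that("no bolus and no noise gives a constant series at S0", {
  acq <- default_acq()
  v <- voxel_truth(0, 0, ttp_ge = 21, ttp_se = 21)
  sim <- simulate_voxel(v, acq)
  expect_equal(sim$signal_ge, rep(1000, acq$n_frames))
  expect_equal(sim$signal_se, rep(800, acq$n_frames))
})

test_that("relaxometry round-trips the generating curve at zero noise", {
  acq <- default_acq()
  v <- healthy_truth()
  sim <- simulate_voxel(v, acq)
  dr_ge <- compute_delta_r(sim$signal_ge,
                           estimate_baseline(sim$signal_ge, 10),
                           acq$te_ge)
  dr_se <- compute_delta_r(sim$signal_se,
                           estimate_baseline(sim$signal_se, 10),
                           acq$te_se)
  expect_lt(max(abs(dr_ge - sim$dr_ge_true)), 1e-10 * v$amplitude_ge)
  expect_lt(max(abs(dr_se - sim$dr_se_true)), 1e-10 * v$amplitude_se)
  # baseline frames carry exactly S0 when noiseless
  expect_equal(mean(sim$signal_ge[1:10]), 1000)
})

test_that("degenerate inputs are rejected with diagnostics", {
  acq <- default_acq()
  expect_error(simulate_voxel(healthy_truth(amp_ge = 25) |>
                                modifyList(list(s0_ge = -5)) |>
                                structure(class = "vam_voxel_truth"),
                              acq),
               "S0 must be positive")
  expect_error(simulate_voxel(healthy_truth(amp_ge = 5000), acq),
               "underflow")
  expect_error(voxel_truth(25, 3.5, ttp_ge = 10, ttp_se = 20),
               "must exceed")
  v <- healthy_truth()
  v$leak_k2 <- 0.02
  expect_error(simulate_voxel(v, acq), "reference_curve")
})

test_that("recovered-curve noise scales proportionally with noise_sd", {
  acq <- default_acq()
  set.seed(42)
  rmse <- sapply(c(2, 4, 8), function(ns) {
    errs <- replicate(40, {
      sim <- simulate_voxel(healthy_truth(noise_sd = ns), acq)
      dr <- compute_delta_r(sim$signal_ge, 1000, acq$te_ge)
      sqrt(mean((dr - sim$dr_ge_true)^2))
    })
    mean(errs)
  })
  expect_equal(rmse[2] / rmse[1], 2, tolerance = 0.15)
  expect_equal(rmse[3] / rmse[2], 2, tolerance = 0.15)
})

test_that("subject simulation is deterministic and respects geometry", {
  acq <- default_acq()
  tr <- region_truth_defaults(noise_sd = 5)
  set.seed(7)
  s1 <- simulate_subject(tr, acq, lesion_side = "left")
  set.seed(7)
  s2 <- simulate_subject(tr, acq, lesion_side = "left")
  expect_identical(s1$signal_ge, s2$signal_ge)
  expect_identical(s1$signal_se, s2$signal_se)
  # VOIs sit in the healthy (right) hemisphere only
  expect_true(all(which(s1$mask > 0, arr.ind = TRUE)[, 1] > 12))
  expect_equal(sort(unique(as.integer(s1$mask))), 0:8)
  # missing region truth is an error
  expect_error(simulate_subject(tr[-1], acq, lesion_side = "left"),
               "no voxel truth")
})

test_that("two regions with identical truths give equal VOI means", {
  set.seed(11)
  v <- healthy_truth(noise_sd = 4)
  sub <- two_region_subject(v, v)
  res <- run_subject(sub)
  vm <- res$voi_means
  for (pn in c("vti", "vips", "rcbv")) {
    m <- vm$mean_value[vm$parameter == pn]
    s <- vm$sd_value[vm$parameter == pn]
    # means agree within a few standard errors of either region
    expect_lt(abs(m[1] - m[2]), 5 * max(s) / sqrt(18) + 1e-12)
  }
})

test_that("doubling a region's GE amplitude raises its rCBV mean", {
  # oracle: the gamma-variate integral is linear in its amplitude
  sub <- two_region_subject(healthy_truth(amp_ge = 12),
                            healthy_truth(amp_ge = 24))
  res <- run_subject(sub)
  vm <- res$voi_means
  rcbv <- vm$mean_value[vm$parameter == "rcbv"]
  expect_gt(rcbv[2], rcbv[1])
  expect_equal(rcbv[2] / rcbv[1], 2, tolerance = 0.02)
})

test_that("cohort demographics match the requested strata", {
  acq <- default_acq()
  spec <- cohort_spec(n_female = 5, n_male = 3, noise_sd = 0, seed = 3,
                      grid_dim = c(18, 22, 4))
  coh <- simulate_cohort(spec, acq)
  expect_equal(sum(coh$demographics$sex == "F"), 5)
  expect_equal(sum(coh$demographics$sex == "M"), 3)
  expect_true(all(coh$demographics$age_years >= 20 &
                    coh$demographics$age_years <= 70))
  expect_equal(nrow(coh$truth), 8 * 8)
  # determinism: the same spec reproduces the cohort bit for bit
  coh2 <- simulate_cohort(spec, acq)
  expect_identical(coh$subjects[[1]]$signal_ge,
                   coh2$subjects[[1]]$signal_ge)
  expect_identical(coh$demographics, coh2$demographics)
})

test_that("an effect referencing an empty sex stratum is rejected", {
  eff <- cohort_effect("amplitude_ge", sex = "M")
  expect_error(cohort_spec(n_female = 5, n_male = 0,
                           effects = list(eff)),
               "empty sex stratum")
  bad <- cohort_effect("amplitude_ge", regions = "not_a_region")
  expect_error(cohort_spec(n_female = 2, n_male = 2,
                           effects = list(bad)),
               "unknown region")
})

test_that("subject NIfTI + JSON round-trip preserves the data", {
  dir <- withr::local_tempdir()
  set.seed(5)
  tr <- region_truth_defaults(noise_sd = 3)
  sub <- simulate_subject(tr, default_acq(), lesion_side = "right",
                          subject_id = "sub-xyz")
  write_subject(sub, dir)
  back <- read_subject(dir, "sub-xyz")
  expect_equal(back$signal_ge, sub$signal_ge, tolerance = 1e-6)
  expect_identical(array(as.integer(back$mask), dim = dim(back$mask)),
                   array(as.integer(sub$mask), dim = dim(sub$mask)))
  expect_equal(back$lesion_side, "right")
  expect_equal(back$acq$tr, 1.5)
})
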