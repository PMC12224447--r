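test_that("loop orientation follows traversal direction", {
  expect_equal(loop_orientation(ellipse_points(1, 1, clockwise = TRUE)),
               1)
  expect_equal(loop_orientation(ellipse_points(1, 1, clockwise = FALSE)),
               -1)
  line <- cbind(seq(0, 1, length.out = 10), 2 * seq(0, 1, length.out = 10))
  expect_equal(loop_orientation(line), 0)
  expect_error(loop_orientation(line[1:2, ]), "3 points")
})

test_that("signed area matches the analytic ellipse area to 0.1%", {
  for (cw in c(TRUE, FALSE)) {
    pts <- ellipse_points(3, 1, n = 1e4, clockwise = cw)
    vti <- compute_vti(pts)
    expect_equal(vti, if (cw) 3 * pi else -3 * pi,
                 tolerance = 1e-3)
  }
  expect_equal(compute_vti(cbind(1:10, 2 * (1:10))), 0)
})

test_that("branch distance on a circle equals the diameter", {
  # circle of radius 2 through the origin, traversal starting there
  th <- seq(pi, 3 * pi, length.out = 4e3)
  pts <- cbind(2 + 2 * cos(th), 2 * sin(th))
  expect_equal(abs(compute_i(pts)), 4, tolerance = 1e-3)
  expect_equal(compute_i(cbind(1:10, 1:10)), 0)
})

test_that("principal axes recover segment and ellipse geometry", {
  # segment of length 5 with slope 2
  tt <- seq(0, 1, length.out = 50)
  seg <- cbind(tt * 5 / sqrt(5), tt * 10 / sqrt(5))
  ax <- principal_axes(seg)
  expect_equal(ax$bvf, 5, tolerance = 1e-9)
  expect_equal(ax$cgi, 2, tolerance = 1e-9)
  expect_equal(ax$cbi, 0, tolerance = 1e-9)

  pts <- ellipse_points(3, 1, n = 1e4)
  ax <- principal_axes(pts)
  expect_equal(ax$bvf, 6, tolerance = 1e-4)
  expect_equal(ax$cbi, 2, tolerance = 1e-4)
  expect_equal(ax$cgi, 0, tolerance = 1e-6)
  expect_error(principal_axes(pts[1:2, ]), "3 points")
})

test_that("axis lengths are rotation invariant", {
  pts <- ellipse_points(3, 1, n = 2000)
  ax0 <- principal_axes(pts)
  for (ang in c(0.3, 1.1, 2.0)) {
    axr <- principal_axes(ellipse_points(3, 1, n = 2000, rotate = ang))
    expect_equal(axr$bvf, ax0$bvf, tolerance = 1e-9)
    expect_equal(axr$cbi, ax0$cbi, tolerance = 1e-9)
  }
})

test_that("SE lead implies counterclockwise loop with negative signs", {
  acq <- default_acq()
  fits <- fit_voxel(simulate_voxel(healthy_truth(lag = -1.5), acq))
  loop <- build_vortex_loop(fits$se, fits$ge)
  expect_equal(loop$orientation, -1)
  expect_lt(compute_vti(loop), 0)
  expect_lt(compute_i(loop), 0)
  expect_lt(compute_vips(fits$se, fits$ge), 0)

  # GE leading flips all three signs
  fits2 <- fit_voxel(simulate_voxel(healthy_truth(lag = +1.5), acq))
  loop2 <- build_vortex_loop(fits2$se, fits2$ge)
  expect_equal(loop2$orientation, 1)
  expect_gt(compute_vti(loop2), 0)
  expect_gt(compute_i(loop2), 0)
  expect_gt(compute_vips(fits2$se, fits2$ge), 0)
})

test_that("time reversal flips the orientation sign", {
  pts <- ellipse_points(2, 1, n = 500, clockwise = TRUE)
  expect_equal(loop_orientation(pts), 1)
  expect_equal(loop_orientation(pts[nrow(pts):1, ]), -1)
})

test_that("identical fits give a degenerate diagonal loop", {
  acq <- default_acq()
  curve <- gamma_variate(acq$time, 5, 15, 3, 2)
  f <- fit_gamma_variate(curve, acq$time)
  loop <- build_vortex_loop(f, f)
  expect_equal(loop$orientation, 0)
  expect_equal(compute_vti(loop), 0)
  expect_equal(compute_vips(f, f), 0)
  # all points on the diagonal
  expect_lt(max(abs(loop$points[, 1] - loop$points[, 2])), 1e-9)
})

test_that("branch separation grows with the SE-GE lag", {
  acq <- default_acq()
  i_abs <- sapply(c(-0.3, -0.6, -1.2), function(lag) {
    fits <- fit_voxel(simulate_voxel(healthy_truth(lag = lag), acq))
    abs(compute_i(build_vortex_loop(fits$se, fits$ge)))
  })
  expect_true(all(diff(i_abs) > 0))
})

test_that("VIPS is the fitted SE-GE time-to-peak difference", {
  acq <- default_acq()
  f_ge <- fit_gamma_variate(gamma_variate(acq$time, 5, 15, 3, 2.2),
                            acq$time)  # ttp 21.6
  f_se <- fit_gamma_variate(gamma_variate(acq$time, 1, 15, 3, 1.7),
                            acq$time)  # ttp 20.1
  expect_equal(compute_vips(f_se, f_ge), -1.5, tolerance = 1e-6)
})

test_that("a sub-frame 0.4 s lag is recovered from TR = 1.5 s data", {
  acq <- default_acq()
  fits <- fit_voxel(simulate_voxel(healthy_truth(lag = -0.4), acq))
  expect_equal(compute_vips(fits$se, fits$ge), -0.4, tolerance = 0.01)
})

test_that("parameters scale correctly under curve scaling", {
  acq <- default_acq()
  base <- fit_voxel(simulate_voxel(healthy_truth(), acq))
  scaled_truth <- healthy_truth(amp_ge = 2.5 * 25, amp_se = 2.5 * 3.5)
  scl <- fit_voxel(simulate_voxel(scaled_truth, acq))
  p0 <- vhl_parameters(base$se, base$ge)
  p1 <- vhl_parameters(scl$se, scl$ge)
  expect_equal(p1$i / p0$i, 2.5, tolerance = 1e-4)
  expect_equal(p1$bvf / p0$bvf, 2.5, tolerance = 1e-4)
  expect_equal(p1$cbi / p0$cbi, 2.5, tolerance = 1e-4)
  expect_equal(p1$vti / p0$vti, 2.5^2, tolerance = 1e-4)
  expect_equal(p1$cgi, p0$cgi, tolerance = 1e-4)
  expect_equal(p1$vips, p0$vips, tolerance = 1e-4)
})

test_that("fast pipeline geometry equals the reference functions", {
  acq <- default_acq()
  set.seed(33)
  for (k in 1:8) {
    lag <- runif(1, -1.2, 1.2)
    fits <- fit_voxel(simulate_voxel(
      healthy_truth(lag = lag, amp_ge = runif(1, 10, 30),
                    amp_se = runif(1, 2, 5)), acq))
    fast <- vamkit:::vhl_numbers(fits$se, fits$ge)
    loop <- build_vortex_loop(fits$se, fits$ge)
    ax <- principal_axes(loop)
    ref <- c(compute_i(loop), compute_vti(loop),
             compute_vips(fits$se, fits$ge), ax$cgi, ax$cbi, ax$bvf,
             loop$orientation)
    expect_equal(unname(fast), ref, tolerance = 1e-9)
  }
})

test_that("loop autoplot returns a ggplot", {
  acq <- default_acq()
  fits <- fit_voxel(simulate_voxel(healthy_truth(), acq))
  p <- autoplot(build_vortex_loop(fits$se, fits$ge))
  expect_s3_class(p, "ggplot")
})
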