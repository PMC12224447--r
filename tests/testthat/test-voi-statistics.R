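test_that("VOI means summarize valid voxels only", {
  map <- array(5, dim = c(4, 4, 2))
  mask <- array(0L, dim = c(4, 4, 2))
  mask[1:2, 1:2, 1] <- 1L
  vm <- voi_mean(map, mask, 1)
  expect_equal(vm$mean, 5)
  expect_equal(vm$sd, 0)
  expect_equal(vm$n_voxels, 4)
  # half the VOI missing: mean over the valid half only
  map[1, 1:2, 1] <- NA
  map[2, 1:2, 1] <- 7
  vm2 <- voi_mean(map, mask, 1)
  expect_equal(vm2$mean, 7)
  expect_equal(vm2$n_voxels, 2)
  expect_error(voi_mean(map, mask, 9), "not present")
  map[2, 1:2, 1] <- NA
  expect_equal(nrow(voi_mean(map, mask, 1)), 0)
})

test_that("ROUT flags nothing on constant or tiny samples", {
  expect_equal(rout_outliers(rep(3.3, 20)), rep(FALSE, 20))
  expect_warning(f <- rout_outliers(1:5), "fewer than 10")
  expect_equal(f, rep(FALSE, 5))
})

test_that("ROUT controls spurious flags and catches gross outliers", {
  set.seed(100)
  spurious <- replicate(200, sum(rout_outliers(rnorm(50))))
  expect_lte(mean(spurious), 1)
  caught <- replicate(200, {
    x <- rnorm(50)
    x[7] <- 10  # 10 sigma plant
    rout_outliers(x)[7]
  })
  expect_gte(mean(caught), 0.99)
})

test_that("omnibus normality statistic matches independent oracle", {
  # frozen reference values computed with an independent implementation
  # (scipy.stats normaltest / skewtest / kurtosistest)
  x <- c(1.2, 0.4, -0.7, 2.2, 0.3, -1.5, 0.8, 0.1, 1.9, -0.2, 0.5,
         1.1, -0.9, 0.2, 0.7, 1.4, -0.3, 0.6, 2.5, -1.1)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 0.09966293137265317, tolerance = 1e-12)
  expect_equal(r$p_value, 0.9513897528089494, tolerance = 1e-12)
  expect_equal(r$z_skew, 0.20433017554898059, tolerance = 1e-12)
  expect_equal(r$z_kurt, -0.24064935223842998, tolerance = 1e-12)

  y <- c(1.4151, 2.0504, 1.1371, 1.7902, 0.4131, 6.7673, 0.0195,
         5.6184, 1.1507, 0.6011, 1.0823, 0.6243, 1.7995, 2.1474,
         3.7685, 0.4441, 6.2893, 1.4717, 0.6967, 1.7671, 0.1501,
         0.1201, 2.4471, 1.5458, 4.3919, 0.9503, 1.0426, 2.3615,
         1.0531, 0.0443)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 13.951877061697502, tolerance = 1e-10)
  expect_equal(r2$z_skew, 3.241260089267331, tolerance = 1e-10)
  expect_equal(r2$z_kurt, 1.8563701396597165, tolerance = 1e-10)
})

test_that("normality gate handles edge cases and skewed data", {
  # perfectly symmetric sample: the skewness component is exactly zero
  x <- rep(c(-1, 0, 1), 6)
  expect_equal(dagostino_pearson(x)$z_skew, 0)
  expect_error(dagostino_pearson(1:5), "n >= 8")
  expect_warning(g <- normality_gate(1:5), "n < 8")
  expect_equal(g, "non_gaussian")
  expect_warning(g2 <- normality_gate(rep(2, 20)), "zero variance")
  expect_equal(g2, "non_gaussian")
  set.seed(12)
  rejected <- replicate(50, normality_gate(rexp(200)) == "non_gaussian")
  expect_gte(mean(rejected), 0.99)
})

test_that("two-group comparison takes the gated path", {
  # identical small groups: gate falls back to Mann-Whitney, p = 1
  a <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(two_group_compare(a, a))
  expect_equal(r$test_name, "mann_whitney")
  expect_equal(r$p_value, 1)
  # label swap leaves p unchanged, flips the effect sign
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25, mean = 1)
  r1 <- two_group_compare(x, y)
  r2 <- two_group_compare(y, x)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$estimate, -r2$estimate)
  expect_equal(r1$test_name, "t")
  expect_equal(nrow(two_group_compare(1, c(2, 3))), 0)
})

test_that("correlation takes the gated path", {
  set.seed(8)
  x <- rnorm(40)
  r <- correlate_gated(x, 2 * x + 3)
  expect_equal(r$estimate, 1)
  expect_equal(r$test_name, "pearson")
  # monotone non-linear: Spearman path gives rho = 1
  xs <- rexp(40)
  rs <- suppressWarnings(correlate_gated(xs, xs^3))
  expect_equal(rs$test_name, "spearman")
  expect_equal(rs$estimate, 1)
  expect_lt(abs(suppressWarnings(cor(xs, xs^3))), 1)
  expect_equal(nrow(correlate_gated(rep(1, 10), rnorm(10))), 0)
})

test_that("null correlations stay below the critical value", {
  set.seed(9)
  hits <- replicate(400, {
    r <- correlate_gated(rnorm(72), rnorm(72))
    abs(r$estimate) < 0.2319  # critical |r| at alpha 0.05, df 70
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.035)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(10)
  n <- 200
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + 0.4 * x + rnorm(n)
  pc <- partial_correlation(x, y, z, method = "pearson")
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  expect_equal(pc$estimate, cor(rx, ry), tolerance = 1e-10)
  # perfect confound: y = z exactly gives partial r = 0
  pc0 <- partial_correlation(x, z, z, method = "pearson")
  expect_equal(nrow(pc0), 0)  # degenerate |r_yz| = 1
  pc1 <- partial_correlation(rnorm(n), z, z, method = "pearson")
  expect_equal(nrow(pc1), 0)
})

test_that("partial r approaches marginal r when z is independent", {
  set.seed(11)
  n <- 1e4
  x <- rnorm(n); y <- 0.3 * x + rnorm(n); z <- rnorm(n)
  pc <- partial_correlation(x, y, z, method = "pearson")
  expect_lt(abs(pc$estimate - cor(x, y)), 0.02)
})

test_that("spearman-path partial correlation uses ranks", {
  set.seed(13)
  n <- 80
  x <- rexp(n); y <- x^2 + rexp(n); z <- rnorm(n)
  pc <- partial_correlation(x, y, z, method = "spearman")
  rx <- residuals(lm(rank(x) ~ rank(z)))
  ry <- residuals(lm(rank(y) ~ rank(z)))
  expect_equal(pc$estimate, cor(rx, ry), tolerance = 1e-10)
})

test_that("BH step-up matches hand-worked and brute-force results", {
  r1 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r1$reject))
  r2 <- bh_fdr(c(0.001, 0.9, 0.9, 0.9), q = 0.05)
  expect_equal(r2$reject, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(r2$q_values >= c(0.001, 0.9, 0.9, 0.9) - 1e-12))
  # exhaustive-subset oracle for random families, m <= 10
  set.seed(14)
  for (k in 1:20) {
    m <- sample(3:10, 1)
    p <- round(runif(m)^2, 4)
    expect_equal(bh_fdr(p, q = 0.05)$reject,
                 bh_bruteforce_reject(p, 0.05))
  }
})
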