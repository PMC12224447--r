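# Shared fixture builders. Everything is generated in code; no files.

default_acq <- function() acquisition_params()

# A clean (noiseless) healthy-tissue voxel: SE leads GE by `lag` s.
healthy_truth <- function(lag = -0.4, noise_sd = 0, amp_ge = 25,
                          amp_se = 3.5, ttp_ge = 21) {
  voxel_truth(amplitude_ge = amp_ge, amplitude_se = amp_se,
              ttp_ge = ttp_ge, ttp_se = ttp_ge + lag,
              noise_sd = noise_sd)
}

# Fit both echoes of a simulated voxel, returning list(se, ge).
fit_voxel <- function(sim, acq = sim$acq) {
  s0g <- estimate_baseline(sim$signal_ge, acq$n_baseline)
  s0s <- estimate_baseline(sim$signal_se, acq$n_baseline)
  list(se = fit_gamma_variate(
         compute_delta_r(sim$signal_se, s0s, acq$te_se), acq$time,
         n_baseline = acq$n_baseline),
       ge = fit_gamma_variate(
         compute_delta_r(sim$signal_ge, s0g, acq$te_ge), acq$time,
         n_baseline = acq$n_baseline))
}

# Ellipse with semi-axes a (x) and b (y), clockwise when clockwise=TRUE.
ellipse_points <- function(a, b, n = 1e4, clockwise = TRUE,
                           rotate = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  if (clockwise) th <- -th
  x <- a * cos(th); y <- b * sin(th)
  if (rotate != 0) {
    xr <- x * cos(rotate) - y * sin(rotate)
    y <- x * sin(rotate) + y * cos(rotate)
    x <- xr
  }
  cbind(x, y)
}

# Two-region subject with explicit truths (region names 1..n as labels).
two_region_subject <- function(truth1, truth2, lesion_side = "left") {
  mask <- array(0L, dim = c(12, 22, 4))
  mask[8:10, 3:5, 2:3] <- 1L
  mask[8:10, 12:14, 2:3] <- 2L
  attr(mask, "region_names") <- c("r1", "r2")
  simulate_subject(list(r1 = truth1, r2 = truth2), default_acq(),
                   mask = mask, lesion_side = lesion_side)
}

# Brute-force Benjamini-Hochberg oracle: the BH rejection set is the
# largest subset S of p-values such that every p in S is at most
# |S| * q / m, taken over all subsets (enumerated exhaustively).
bh_bruteforce_reject <- function(p, q) {
  m <- length(p)
  best_size <- 0L
  for (code in 0:(2^m - 1)) {
    members <- as.logical(bitwAnd(code, 2^(0:(m - 1))))
    k <- sum(members)
    if (k <= best_size) next
    if (all(p[members] <= k * q / m)) best_size <- k
  }
  # the step-up set consists of the best_size smallest p-values
  if (best_size == 0L) return(logical(m))
  rank(p, ties.method = "first") <= best_size
}
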