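#' Baseline signal estimate
#'
#' Arithmetic mean of the first `n_baseline` pre-bolus frames.
#'
#' @param signal Numeric per-voxel signal series.
#' @param n_baseline Number of baseline frames (>= 3).
#' @return The baseline signal S0.
#' @export
estimate_baseline <- function(signal, n_baseline) {
  if (n_baseline < 3) stop("n_baseline must be >= 3")
  if (length(signal) < n_baseline)
    stop("signal shorter than the baseline window")
  mean(signal[seq_len(n_baseline)])
}

#' Relaxation-rate change curve from a signal series
#'
#' `dR(t) = -(1/TE) * log(S(t) / S0)`, elementwise. Voxels with any
#' non-positive signal frame are flagged invalid (values set to `NA`)
#' rather than clipped.
#'
#' @param signal Numeric signal series, arbitrary units.
#' @param s0 Baseline signal (> 0).
#' @param te Echo time, seconds (> 0).
#' @return Numeric curve in 1/s with attribute `valid` (logical).
#' @examples
#' compute_delta_r(1000 * exp(-0.9), s0 = 1000, te = 0.090)  # 10 1/s
#' @export
compute_delta_r <- function(signal, s0, te) {
  if (s0 <= 0) stop("S0 must be positive")
  if (te <= 0) stop("TE must be positive")
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    out <- rep(NA_real_, length(signal))
    attr(out, "valid") <- FALSE
    return(out)
  }
  out <- -(1 / te) * log(signal / s0)
  attr(out, "valid") <- TRUE
  out
}

#' Contrast-agent leakage correction
#'
#' Fits the measured dR2* curve to the two-parameter extravasation
#' model `measured(t) ~ K1 * ref(t) - K2 * int_0^t ref(tau) dtau` by
#' ordinary least squares against a whole-brain reference curve, and
#' returns the corrected curve `measured(t) + K2 * int_0^t ref`.
#'
#' @param curve Measured dR2* series, 1/s.
#' @param reference Reference dR2* curve (baseline-zeroed whole-brain
#'   mean), 1/s, same length as `curve`.
#' @param time Sample times, seconds.
#' @return A list: `corrected` (curve, 1/s), `k1`, `k2` (1/s),
#'   `residual_variance`.
#' @export
leakage_correct <- function(curve, reference, time) {
  stopifnot(length(curve) == length(reference),
            length(curve) == length(time))
  if (all(abs(reference) < 1e-300) || sd(reference) == 0)
    stop("degenerate reference curve (all zero)")
  cum_ref <- pracma::cumtrapz(time, reference)[, 1]
  x <- cbind(reference, -cum_ref)
  fit <- lm.fit(x, curve)
  k1 <- unname(fit$coefficients[1])
  k2 <- unname(fit$coefficients[2])
  if (!is.finite(k2)) k2 <- 0
  if (!is.finite(k1)) k1 <- 0
  list(corrected = curve + k2 * cum_ref, k1 = k1, k2 = k2,
       residual_variance = mean(fit$residuals^2))
}

gamma_fit_bounds <- function(time) {
  list(lower = c(log(1e-8), 0, log(0.2), log(0.05)),
       upper = c(log(1e8), max(time), log(30), log(60)))
}

# Model and analytic partials on transformed parameters
# p = (log A, t0, log alpha, log beta); returns list(f, d1..d4), each
# a length(t) vector (or T x V matrix when p entries are row vectors).
gamma_model_parts <- function(time, loga, t0, lalpha, lbeta) {
  nt <- length(time)
  alpha <- rep(exp(lalpha), each = nt)
  beta <- rep(exp(lbeta), each = nt)
  u <- time - rep(t0, each = nt)
  dim(u) <- c(nt, length(t0))
  pos <- u > 1e-9
  u[!pos] <- 1e-9
  lu <- log(u)
  f <- exp(rep(loga, each = nt) + alpha * lu - u / beta)
  f[!pos] <- 0
  list(f = f,
       d1 = f,
       d2 = -f * (alpha / u - 1 / beta),
       d3 = f * alpha * lu,
       d4 = f * u / beta)
}

# Batched Cholesky solve of many symmetric positive-definite 4x4
# systems at once (one per voxel); returns a 4 x n matrix of
# solutions, with zero steps where the factorization fails.
chol4_solve <- function(a11, a12, a13, a14, a22, a23, a24,
                        a33, a34, a44, b1, b2, b3, b4) {
  bad <- a11 <= 0
  l11 <- sqrt(pmax(a11, 1e-300))
  l21 <- a12 / l11; l31 <- a13 / l11; l41 <- a14 / l11
  d2 <- a22 - l21^2; bad <- bad | d2 <= 0
  l22 <- sqrt(pmax(d2, 1e-300))
  l32 <- (a23 - l31 * l21) / l22
  l42 <- (a24 - l41 * l21) / l22
  d3 <- a33 - l31^2 - l32^2; bad <- bad | d3 <= 0
  l33 <- sqrt(pmax(d3, 1e-300))
  l43 <- (a34 - l41 * l31 - l42 * l32) / l33
  d4 <- a44 - l41^2 - l42^2 - l43^2; bad <- bad | d4 <= 0
  l44 <- sqrt(pmax(d4, 1e-300))
  # forward substitution L y = b
  y1 <- b1 / l11
  y2 <- (b2 - l21 * y1) / l22
  y3 <- (b3 - l31 * y1 - l32 * y2) / l33
  y4 <- (b4 - l41 * y1 - l42 * y2 - l43 * y3) / l44
  # back substitution L' x = y
  x4 <- y4 / l44
  x3 <- (y3 - l43 * x4) / l33
  x2 <- (y2 - l32 * x3 - l42 * x4) / l22
  x1 <- (y1 - l21 * x2 - l31 * x3 - l41 * x4) / l11
  out <- rbind(x1, x2, x3, x4)
  out[, bad | !is.finite(colSums(out))] <- 0
  out[!is.finite(out)] <- 0
  out
}

# Vectorized Levenberg-Marquardt gamma-variate fit over many voxels.
# y: frames x voxels matrix of relaxation curves; returns per-voxel
# parameter estimates. Used by the volume pipeline for throughput; the
# single-voxel minpack.lm path is the reference implementation.
fit_gamma_batch <- function(y, time, n_baseline,
                            peak_snr_min = 3, r2_min = 0.6,
                            max_iter = 100) {
  y <- as.matrix(y)
  nt <- nrow(y); nv <- ncol(y)
  stopifnot(length(time) == nt, n_baseline >= 3)

  base_sd <- apply(y[seq_len(n_baseline), , drop = FALSE], 2, sd)
  ipk <- max.col(t(y), ties.method = "first")
  peak <- y[cbind(ipk, seq_len(nv))]
  tpk <- time[ipk]
  fit_ok <- is.finite(peak) & peak > pmax(peak_snr_min * base_sd, 1e-6)

  # t0 init: last sample before the peak below 10% of peak height
  t0 <- numeric(nv)
  tr <- time[2] - time[1]
  for (v in seq_len(nv)) {
    if (!fit_ok[v]) next
    below <- which(y[seq_len(ipk[v]), v] < 0.1 * peak[v])
    t0[v] <- if (length(below)) time[max(below)] else max(tpk[v] - 6 * tr, 0)
  }
  t0 <- pmin(t0, tpk - 2 * tr)
  t0 <- pmax(t0, 0)

  alpha0 <- rep(3, nv)
  beta0 <- pmax((tpk - t0) / alpha0, 0.05)
  loga <- log(pmax(peak, 1e-8)) -
    alpha0 * log(pmax(alpha0 * beta0, 1e-9)) + alpha0
  p <- rbind(loga, t0, log(alpha0), log(beta0))

  b <- gamma_fit_bounds(time)
  clamp <- function(p) {
    p[1, ] <- pmin(pmax(p[1, ], b$lower[1]), b$upper[1])
    p[2, ] <- pmin(pmax(p[2, ], b$lower[2]), pmin(tpk - 1e-3, b$upper[2]))
    p[3, ] <- pmin(pmax(p[3, ], b$lower[3]), b$upper[3])
    p[4, ] <- pmin(pmax(p[4, ], b$lower[4]), b$upper[4])
    p
  }
  p <- clamp(p)

  active <- which(fit_ok)
  lambda <- rep(1e-3, nv)
  parts <- gamma_model_parts(time, p[1, ], p[2, ], p[3, ], p[4, ])
  resid <- parts$f - y
  sse <- colSums(resid^2)

  for (iter in seq_len(max_iter)) {
    if (!length(active)) break
    d1 <- parts$d1[, active, drop = FALSE]
    d2 <- parts$d2[, active, drop = FALSE]
    d3 <- parts$d3[, active, drop = FALSE]
    d4 <- parts$d4[, active, drop = FALSE]
    r <- resid[, active, drop = FALSE]
    a11 <- colSums(d1 * d1); a12 <- colSums(d1 * d2)
    a13 <- colSums(d1 * d3); a14 <- colSums(d1 * d4)
    a22 <- colSums(d2 * d2); a23 <- colSums(d2 * d3)
    a24 <- colSums(d2 * d4); a33 <- colSums(d3 * d3)
    a34 <- colSums(d3 * d4); a44 <- colSums(d4 * d4)
    g1 <- colSums(d1 * r); g2 <- colSums(d2 * r)
    g3 <- colSums(d3 * r); g4 <- colSums(d4 * r)

    lam <- lambda[active]
    step <- chol4_solve(
      a11 + lam * pmax(a11, 1e-12), a12, a13, a14,
      a22 + lam * pmax(a22, 1e-12), a23, a24,
      a33 + lam * pmax(a33, 1e-12), a34,
      a44 + lam * pmax(a44, 1e-12),
      -g1, -g2, -g3, -g4)
    p_new <- p
    p_new[, active] <- p[, active] + step
    p_new <- clamp(p_new)
    parts_new <- gamma_model_parts(time, p_new[1, active], p_new[2, active],
                                   p_new[3, active], p_new[4, active])
    resid_new <- parts_new$f - y[, active, drop = FALSE]
    sse_new <- colSums(resid_new^2)
    improved <- is.finite(sse_new) & (sse_new < sse[active])
    iv <- active[improved]
    done <- integer(0)
    if (length(iv)) {
      p[, iv] <- p_new[, iv]
      resid[, iv] <- resid_new[, improved, drop = FALSE]
      parts$f[, iv] <- parts_new$f[, improved, drop = FALSE]
      parts$d1[, iv] <- parts_new$d1[, improved, drop = FALSE]
      parts$d2[, iv] <- parts_new$d2[, improved, drop = FALSE]
      parts$d3[, iv] <- parts_new$d3[, improved, drop = FALSE]
      parts$d4[, iv] <- parts_new$d4[, improved, drop = FALSE]
      rel <- (sse[iv] - sse_new[improved]) / pmax(sse[iv], 1e-300)
      sse[iv] <- sse_new[improved]
      lambda[iv] <- pmax(lambda[iv] / 3, 1e-10)
      done <- iv[rel < 1e-12]
    }
    stalled <- setdiff(active, iv)
    lambda[stalled] <- pmin(lambda[stalled] * 5, 1e8)
    active <- setdiff(active, done)
    active <- active[lambda[active] < 1e8]
  }

  a <- exp(p[1, ]); t0 <- p[2, ]; alpha <- exp(p[3, ]); beta <- exp(p[4, ])
  ttp <- t0 + alpha * beta
  fitted_peak <- gamma_variate_peak(a, alpha, beta)
  ss_tot <- colSums(sweep(y, 2, colMeans(y), "-")^2)
  r2 <- 1 - sse / pmax(ss_tot, 1e-300)
  valid <- fit_ok & is.finite(r2) & r2 >= r2_min
  list(a = a, t0 = t0, alpha = alpha, beta = beta, ttp = ttp,
       peak = fitted_peak, r2 = r2, valid = valid)
}

#' Fit a gamma-variate bolus model to one relaxation curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of `A * (t - t0)^alpha * exp(-(t - t0)/beta)`
#' against a relaxation-rate change curve, with a method-of-moments
#' start (bolus arrival from the first crossing of 10% of peak) and
#' multi-start over the shape parameter. Curves whose peak does not
#' exceed `peak_snr_min` baseline noise SDs, or whose best fit has
#' `r2 < r2_min`, are flagged invalid rather than raising an error.
#'
#' @param curve Relaxation-rate change series, 1/s.
#' @param time Sample times, seconds (uniform grid).
#' @param n_baseline Baseline frames used for the noise estimate.
#' @param peak_snr_min Peak-to-baseline-noise gate (default 3).
#' @param r2_min Minimum goodness-of-fit to accept (default 0.6).
#' @return A `vam_gamma_fit`: list with `a`, `t0`, `alpha`, `beta`,
#'   `ttp` (`= t0 + alpha * beta`), `peak` (fitted maximum, 1/s), `r2`,
#'   `valid`, `fitted` (curve on `time`), `time`.
#' @examples
#' acq <- acquisition_params()
#' cur <- gamma_variate(acq$time, 1.2, 15, 3, 2)
#' fit <- fit_gamma_variate(cur, acq$time)
#' c(fit$ttp, fit$r2)
#' @export
fit_gamma_variate <- function(curve, time, n_baseline = 10,
                              peak_snr_min = 3, r2_min = 0.6) {
  stopifnot(length(curve) == length(time))
  invalid <- function() {
    structure(list(a = NA_real_, t0 = NA_real_, alpha = NA_real_,
                   beta = NA_real_, ttp = NA_real_, peak = NA_real_,
                   r2 = NA_real_, valid = FALSE,
                   fitted = rep(NA_real_, length(time)), time = time),
              class = "vam_gamma_fit")
  }
  if (any(!is.finite(curve))) return(invalid())
  base_sd <- sd(curve[seq_len(min(n_baseline, length(curve)))])
  peak <- max(curve)
  if (peak <= max(peak_snr_min * base_sd, 1e-6)) return(invalid())

  ipk <- which.max(curve)
  tpk <- time[ipk]
  tr <- time[2] - time[1]
  below <- which(curve[seq_len(ipk)] < 0.1 * peak)
  t0_init <- if (length(below)) time[max(below)] else max(tpk - 6 * tr, 0)
  t0_init <- max(min(t0_init, tpk - 2 * tr), 0)

  b <- gamma_fit_bounds(time)
  resid_fn <- function(p) {
    alpha <- exp(p[3]); beta <- exp(p[4])
    gamma_variate(time, exp(p[1]), p[2], alpha, beta) - curve
  }
  best <- NULL
  for (alpha0 in c(1.5, 3, 6)) {
    beta0 <- max((tpk - t0_init) / alpha0, 0.05)
    loga0 <- log(peak) - alpha0 * log(alpha0 * beta0) + alpha0
    start <- c(loga0, t0_init, log(alpha0), log(beta0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         lower = b$lower,
                         upper = pmin(b$upper, c(Inf, tpk - 1e-3, Inf, Inf)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(invalid())
  p <- best$fit$par
  a <- exp(p[1]); t0 <- p[2]; alpha <- exp(p[3]); beta <- exp(p[4])
  ss_tot <- sum((curve - mean(curve))^2)
  r2 <- 1 - best$sse / max(ss_tot, 1e-300)
  fitted <- gamma_variate(time, a, t0, alpha, beta)
  structure(
    list(a = a, t0 = t0, alpha = alpha, beta = beta,
         ttp = t0 + alpha * beta,
         peak = gamma_variate_peak(a, alpha, beta),
         r2 = r2, valid = is.finite(r2) && r2 >= r2_min,
         fitted = fitted, time = time),
    class = "vam_gamma_fit"
  )
}

#' @export
print.vam_gamma_fit <- function(x, ...) {
  if (!x$valid) {
    cat("<vam_gamma_fit> invalid\n")
  } else {
    cat(sprintf(
      "<vam_gamma_fit> peak = %.3g 1/s at ttp = %.3g s (t0 = %.3g, alpha = %.3g, beta = %.3g), r2 = %.4f\n",
      x$peak, x$ttp, x$t0, x$alpha, x$beta, x$r2))
  }
  invisible(x)
}

#' @rdname fit_gamma_variate
#' @param x A `vam_gamma_fit`.
#' @param ... Unused.
#' @export
tidy.vam_gamma_fit <- function(x, ...) {
  tibble(term = c("a", "t0", "alpha", "beta"),
         estimate = c(x$a, x$t0, x$alpha, x$beta))
}

#' @rdname fit_gamma_variate
#' @export
glance.vam_gamma_fit <- function(x, ...) {
  tibble(r.squared = x$r2, ttp = x$ttp, peak = x$peak, valid = x$valid)
}
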