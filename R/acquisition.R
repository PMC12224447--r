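#' Acquisition timing parameters for a dual-echo dynamic series
#'
#' Bundles the timing constants of a spin-and-gradient-echo (SAGE) EPI
#' bolus acquisition: repetition time, the two echo times, and the frame
#' layout (pre-bolus baseline frames followed by bolus-passage frames).
#' Defaults correspond to a 1.5 min acquisition sampled at TR = 1.5 s
#' (15 s baseline, 75 s bolus passage) with TE = 22 ms (gradient echo)
#' and TE = 90 ms (spin echo).
#'
#' @param tr Repetition time in seconds.
#' @param te_ge Gradient-echo time in seconds; must be positive and
#'   smaller than `te_se`.
#' @param te_se Spin-echo time in seconds.
#' @param n_baseline Number of pre-bolus baseline frames.
#' @param n_frames Total number of frames in the series.
#'
#' @return An object of class `vam_acq`: a list with the five timing
#'   fields plus `time`, the frame-onset times in seconds
#'   (`0, tr, ..., (n_frames - 1) * tr`).
#' @examples
#' acq <- acquisition_params()
#' range(acq$time)
#' @export
acquisition_params <- function(tr = 1.5, te_ge = 0.022, te_se = 0.090,
                               n_baseline = 10, n_frames = 60) {
  stopifnot(tr > 0, te_ge > 0, te_se > te_ge,
            n_baseline >= 1, n_frames > n_baseline)
  structure(
    list(tr = tr, te_ge = te_ge, te_se = te_se,
         n_baseline = as.integer(n_baseline),
         n_frames = as.integer(n_frames),
         time = (seq_len(n_frames) - 1) * tr),
    class = "vam_acq"
  )
}

#' @export
print.vam_acq <- function(x, ...) {
  cat(sprintf(
    "<vam_acq> TR = %g s, TE = %g ms (GE) / %g ms (SE), %d baseline + %d bolus frames (%g s total)\n",
    x$tr, 1e3 * x$te_ge, 1e3 * x$te_se, x$n_baseline,
    x$n_frames - x$n_baseline, x$n_frames * x$tr))
  invisible(x)
}

#' Gamma-variate bolus curve
#'
#' The standard gamma-variate model of a first-pass contrast bolus:
#' `C(t) = A * (t - t0)^alpha * exp(-(t - t0) / beta)` for `t > t0` and 0
#' otherwise. Its maximum lies at `t = t0 + alpha * beta` with value
#' `A * (alpha * beta)^alpha * exp(-alpha)`.
#'
#' @param t Numeric vector of times, seconds.
#' @param a Amplitude scale `A` (units of the curve times s^-alpha).
#' @param t0 Bolus arrival time, seconds.
#' @param alpha Shape parameter, dimensionless, > 0.
#' @param beta Scale parameter, seconds, > 0.
#' @return Numeric vector of curve values at `t`.
#' @examples
#' t <- seq(0, 90, by = 1.5)
#' plot(t, gamma_variate(t, a = 1, t0 = 15, alpha = 3, beta = 2), type = "l")
#' @export
gamma_variate <- function(t, a, t0, alpha, beta) {
  u <- t - t0
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- a * u[pos]^alpha * exp(-u[pos] / beta)
  out
}

#' @rdname gamma_variate
#' @export
gamma_variate_peak <- function(a, alpha, beta) {
  a * (alpha * beta)^alpha * exp(-alpha)
}

# Amplitude scale A that gives a gamma-variate the requested peak height.
gamma_scale_for_peak <- function(peak, alpha, beta) {
  peak / ((alpha * beta)^alpha * exp(-alpha))
}
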