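# Vascular hysteresis loop (vortex curve) geometry.
#
# Axis convention used throughout: x = dR2 (spin echo), y = dR2*
# (gradient echo). With this convention a spin-echo curve peaking
# before the gradient-echo curve traces the loop counterclockwise,
# and counterclockwise traversal is signed negative.

as_loop_points <- function(x) {
  if (inherits(x, "vam_vhl_loop")) return(x$points)
  m <- as.matrix(x)
  stopifnot(ncol(m) == 2)
  m
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Traversal direction of a closed loop
#'
#' Sign of the loop's traversal in the (dR2, dR2*) plane: `+1` for
#' clockwise, `-1` for counterclockwise, `0` when the enclosed
#' (shoelace) area is below `tol` (degenerate loop). Clockwise loops
#' carry positive vascular-parameter signs.
#'
#' @param loop A `vam_vhl_loop` or an n x 2 matrix of (x, y) points in
#'   traversal order.
#' @param tol Degeneracy tolerance on the absolute shoelace area,
#'   (1/s)^2.
#' @return `+1`, `-1` or `0`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)
#' loop_orientation(cbind(cos(-th), sin(-th)))  # clockwise: +1
#' @export
loop_orientation <- function(loop, tol = 1e-12) {
  pts <- as_loop_points(loop)
  if (nrow(pts) < 3) stop("need at least 3 points")
  a <- shoelace_area(pts)
  if (abs(a) < tol) return(0)
  # shoelace > 0 means counterclockwise in standard orientation
  -sign(a)
}

#' Build the vascular hysteresis loop from a fitted curve pair
#'
#' Samples both gamma-variate fits on a common dense time grid
#' (`oversample` times the acquisition rate, at least 200 points) from
#' the earlier bolus arrival to the end of the series, pairs them as
#' (x = dR2 from the spin echo, y = dR2* from the gradient echo), and
#' closes the polygon at the origin (both tails decay toward baseline).
#'
#' @param fit_se,fit_ge Valid [fit_gamma_variate()] results for the
#'   spin-echo and gradient-echo curves.
#' @param oversample Dense-grid factor relative to the acquisition
#'   frame rate.
#' @param tol Degeneracy tolerance passed to [loop_orientation()].
#' @return A `vam_vhl_loop`: `points` (n x 2), `time`, `orientation`,
#'   `peak_split_index` (index of maximum distance from the origin,
#'   separating ascending from descending branch), `area` (signed
#'   shoelace), `ttp_se`, `ttp_ge`.
#' @export
build_vortex_loop <- function(fit_se, fit_ge, oversample = 4,
                              tol = 1e-12) {
  if (!isTRUE(fit_se$valid) || !isTRUE(fit_ge$valid))
    stop("both fits must be valid to build a loop")
  time <- fit_se$time
  dt <- (time[2] - time[1]) / oversample
  t_start <- min(fit_se$t0, fit_ge$t0)
  n <- max(200L, ceiling((max(time) - t_start) / dt) + 1L)
  grid <- seq(t_start, max(time), length.out = n)
  x <- gamma_variate(grid, fit_se$a, fit_se$t0, fit_se$alpha, fit_se$beta)
  y <- gamma_variate(grid, fit_ge$a, fit_ge$t0, fit_ge$alpha, fit_ge$beta)
  pts <- cbind(x = x, y = y)
  if (sqrt(sum(pts[n, ]^2)) > 1e-12) pts <- rbind(pts, c(0, 0))
  structure(
    list(points = pts, time = grid,
         orientation = loop_orientation(pts, tol),
         peak_split_index = which.max(rowSums(pts^2)),
         area = shoelace_area(pts),
         ttp_se = fit_se$ttp, ttp_ge = fit_ge$ttp),
    class = "vam_vhl_loop"
  )
}

#' @export
print.vam_vhl_loop <- function(x, ...) {
  cat(sprintf(
    "<vam_vhl_loop> %d points, orientation %+d, area %.4g (1/s)^2\n",
    nrow(x$points), x$orientation, x$area))
  invisible(x)
}

#' Vessel type indicator: signed loop area
#'
#' Enclosed area of the hysteresis loop by the shoelace formula, signed
#' by traversal direction (clockwise positive, counterclockwise
#' negative). Healthy tissue, where the spin echo leads, gives negative
#' values.
#'
#' @inheritParams loop_orientation
#' @return Signed area, (1/s)^2.
#' @export
compute_vti <- function(loop, tol = 1e-12) {
  pts <- as_loop_points(loop)
  ori <- loop_orientation(pts, tol)
  if (ori == 0) return(0)
  ori * abs(shoelace_area(pts))
}

#' Distance map I: signed maximum branch separation
#'
#' Splits the loop into ascending and descending branches at the point
#' farthest from the origin, resamples both branches at common dR2
#' (x) values over their overlapping range, and returns the signed
#' maximum vertical (dR2*) separation, with the loop's traversal sign.
#'
#' @inheritParams loop_orientation
#' @param n_resample Number of common x-values used to compare the
#'   branches.
#' @return Signed distance, 1/s (`0` for degenerate loops, `NA` if the
#'   branches share no x-range).
#' @export
compute_i <- function(loop, tol = 1e-12, n_resample = 200) {
  pts <- as_loop_points(loop)
  ori <- loop_orientation(pts, tol)
  if (ori == 0) return(0)
  split <- if (inherits(loop, "vam_vhl_loop")) loop$peak_split_index
           else which.max(rowSums(pts^2))
  asc <- pts[seq_len(split), , drop = FALSE]
  desc <- pts[split:nrow(pts), , drop = FALSE]
  lo <- max(min(asc[, 1]), min(desc[, 1]))
  hi <- min(max(asc[, 1]), max(desc[, 1]))
  if (!(hi > lo)) return(NA_real_)
  xs <- seq(lo, hi, length.out = n_resample)
  ya <- approx(asc[, 1], asc[, 2], xout = xs, ties = mean)$y
  yd <- approx(desc[, 1], desc[, 2], xout = xs, ties = mean)$y
  ori * max(abs(yd - ya), na.rm = TRUE)
}

#' Principal axes of the hysteresis loop
#'
#' Principal-component decomposition of the loop's point cloud. The
#' long axis is the first principal direction: its projection range is
#' the blood-volume-fraction correlate BVF, its slope (dR2* change per
#' dR2 change) the caliber gradient indicator CGI, and the projection
#' range on the orthogonal direction is the capillary bed identifier
#' CBI. Collinear point sets are allowed (CBI = 0).
#'
#' @inheritParams loop_orientation
#' @return A list with `bvf` (1/s), `cgi` (dimensionless), `cbi`
#'   (1/s).
#' @export
principal_axes <- function(loop) {
  pts <- as_loop_points(loop)
  if (nrow(pts) < 3) stop("need at least 3 points")
  ctr <- sweep(pts, 2, colMeans(pts))
  cv <- crossprod(ctr) / (nrow(pts) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  v2 <- eg$vectors[, 2]
  p1 <- ctr %*% v1
  p2 <- ctr %*% v2
  list(bvf = diff(range(p1)),
       cgi = if (abs(v1[1]) < 1e-15) Inf else v1[2] / v1[1],
       cbi = diff(range(p2)))
}

#' Vascular-induced bolus peak-time shift
#'
#' Time-to-peak of the spin-echo curve minus time-to-peak of the
#' gradient-echo curve, from the fitted (continuous) times-to-peak.
#' Negative values indicate a spin-echo lead, i.e. relative
#' predominance of slow-flowing venules and capillaries.
#'
#' @param fit_se,fit_ge Valid [fit_gamma_variate()] results.
#' @return Shift in seconds.
#' @export
compute_vips <- function(fit_se, fit_ge) {
  if (!isTRUE(fit_se$valid) || !isTRUE(fit_ge$valid)) return(NA_real_)
  fit_se$ttp - fit_ge$ttp
}

# Numeric core shared by vhl_parameters() and the volume pipeline:
# returns c(i, vti, vips, cgi, cbi, bvf, orientation). Same geometry
# as build_vortex_loop() + compute_*() + principal_axes(), written
# without intermediate objects so the voxelwise pipeline stays fast;
# equality with the reference path is covered by tests.
vhl_numbers <- function(fit_se, fit_ge, oversample = 4,
                        tol = 1e-12, n_resample = 200) {
  time <- fit_se$time
  dt <- (time[2] - time[1]) / oversample
  t_start <- min(fit_se$t0, fit_ge$t0)
  n <- max(200L, ceiling((max(time) - t_start) / dt) + 1L)
  grid <- seq(t_start, max(time), length.out = n)
  x <- gamma_variate(grid, fit_se$a, fit_se$t0, fit_se$alpha, fit_se$beta)
  y <- gamma_variate(grid, fit_ge$a, fit_ge$t0, fit_ge$alpha, fit_ge$beta)
  if (x[n]^2 + y[n]^2 > 1e-24) { x <- c(x, 0); y <- c(y, 0); n <- n + 1L }

  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- 0.5 * sum(x * yn - xn * y)
  ori <- if (abs(area) < tol) 0 else -sign(area)
  vti <- if (ori == 0) 0 else ori * abs(area)

  i_val <- 0
  if (ori != 0) {
    split <- which.max(x^2 + y^2)
    ia <- seq_len(split); id <- split:n
    lo <- max(min(x[ia]), min(x[id]))
    hi <- min(max(x[ia]), max(x[id]))
    if (hi > lo) {
      xs <- seq(lo, hi, length.out = n_resample)
      ya <- approx(x[ia], y[ia], xout = xs, ties = mean)$y
      yd <- approx(x[id], y[id], xout = xs, ties = mean)$y
      i_val <- ori * max(abs(yd - ya), na.rm = TRUE)
    } else i_val <- NA_real_
  }

  cx <- x - mean(x); cy <- y - mean(y)
  cxx <- sum(cx * cx); cyy <- sum(cy * cy); cxy <- sum(cx * cy)
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  ct <- cos(theta); st <- sin(theta)
  p1 <- cx * ct + cy * st
  p2 <- -cx * st + cy * ct
  c(i = i_val, vti = vti, vips = fit_se$ttp - fit_ge$ttp,
    cgi = if (abs(ct) < 1e-15) Inf else st / ct,
    cbi = max(p2) - min(p2), bvf = max(p1) - min(p1),
    orientation = ori)
}

#' All six hysteresis-loop parameters for one voxel
#'
#' Convenience wrapper: builds the loop from the fitted curve pair and
#' returns the six geometric parameters in one row.
#'
#' @inheritParams build_vortex_loop
#' @return A one-row tibble: `i`, `vti`, `vips`, `cgi`, `cbi`, `bvf`,
#'   `orientation` (all `NA` if either fit is invalid).
#' @export
vhl_parameters <- function(fit_se, fit_ge, oversample = 4) {
  if (!isTRUE(fit_se$valid) || !isTRUE(fit_ge$valid)) {
    return(tibble(i = NA_real_, vti = NA_real_, vips = NA_real_,
                  cgi = NA_real_, cbi = NA_real_, bvf = NA_real_,
                  orientation = NA_real_))
  }
  v <- vhl_numbers(fit_se, fit_ge, oversample)
  tibble(i = v[["i"]], vti = v[["vti"]], vips = v[["vips"]],
         cgi = v[["cgi"]], cbi = v[["cbi"]], bvf = v[["bvf"]],
         orientation = v[["orientation"]])
}

#' Plot a vascular hysteresis loop
#'
#' @param object A `vam_vhl_loop`.
#' @param ... Unused.
#' @return A ggplot: the loop path in the (dR2, dR2*) plane, colored by
#'   time, annotated with its orientation.
#' @export
autoplot.vam_vhl_loop <- function(object, ...) {
  df <- tibble(x = object$points[, 1], y = object$points[, 2],
               t = c(object$time,
                     rep(max(object$time),
                         nrow(object$points) - length(object$time))))
  dir_lab <- c(`-1` = "counterclockwise (SE leads)", `0` = "degenerate",
               `1` = "clockwise (GE leads)")[as.character(object$orientation)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$t)) +
    ggplot2::geom_path(arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                                              ends = "last")) +
    ggplot2::labs(x = expression(Delta * R[2] ~ "(1/s)"),
                  y = expression(Delta * R[2]^"*" ~ "(1/s)"),
                  colour = "time (s)",
                  title = "Vascular hysteresis loop",
                  subtitle = dir_lab) +
    ggplot2::theme_minimal()
}
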