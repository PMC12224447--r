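#' Physical constants for vessel size imaging
#'
#' Constants entering the vessel size index: gyromagnetic ratio,
#' blood-tissue susceptibility difference at full contrast
#' concentration, main field strength, and the water apparent diffusion
#' coefficient (scalar default; a per-voxel map may be substituted).
#'
#' @param gamma Gyromagnetic ratio of the proton, rad/(s T).
#' @param delta_chi Susceptibility difference, dimensionless (SI).
#' @param b0 Field strength, tesla.
#' @param adc Apparent diffusion coefficient, mm^2/s.
#' @return A `vam_constants` list.
#' @export
physical_constants <- function(gamma = 2.67513e8, delta_chi = 1e-7,
                               b0 = 3, adc = 0.8e-3) {
  stopifnot(gamma > 0, delta_chi > 0, b0 > 0, adc > 0)
  structure(list(gamma = gamma, delta_chi = delta_chi, b0 = b0,
                 adc = adc),
            class = "vam_constants")
}

#' Microvessel density index Q
#'
#' `Q = dR2 / (dR2*)^(2/3)`, in s^(-1/3), from the fitted peak
#' relaxation-rate changes. Table-style reporting units
#' (10^2 ms^(-1/3)) are a separate conversion, [q_table_units()].
#'
#' @param dr2_peak Peak dR2 (spin echo), 1/s, >= 0.
#' @param dr2star_peak Peak dR2* (gradient echo), 1/s, > 0.
#' @return Q in s^(-1/3); `NA` where `dr2star_peak <= 0`.
#' @examples
#' compute_q(8, 8)  # 2
#' @export
compute_q <- function(dr2_peak, dr2star_peak) {
  out <- dr2_peak / dr2star_peak^(2 / 3)
  out[!is.finite(out) | dr2star_peak <= 0 | dr2_peak < 0] <- NA_real_
  out
}

#' @rdname compute_q
#' @param q Q in s^(-1/3).
#' @export
q_table_units <- function(q) {
  # s^(-1/3) -> ms^(-1/3) divides by 10; reporting in 10^2 ms^(-1/3)
  # multiplies by 100
  q * 10
}

#' Vessel size index
#'
#' `VSI = 0.425 * (ADC / (gamma * delta_chi * B0))^(1/2)
#'  * (dR2* / dR2)^(3/2)`, in micrometres (ADC is converted from
#' mm^2/s to um^2/s internally; `gamma * delta_chi * B0` has units
#' 1/s). Monotone increasing in the dR2*/dR2 ratio, i.e. in mean
#' vessel caliber.
#'
#' @param dr2star_peak Peak dR2* (gradient echo), 1/s, > 0.
#' @param dr2_peak Peak dR2 (spin echo), 1/s, > 0.
#' @param constants A [physical_constants()].
#' @return VSI in micrometres; `NA` where either peak is non-positive.
#' @export
compute_vsi <- function(dr2star_peak, dr2_peak,
                        constants = physical_constants()) {
  stopifnot(inherits(constants, "vam_constants"))
  adc_um2 <- constants$adc * 1e6
  scale <- 0.425 * sqrt(adc_um2 /
                          (constants$gamma * constants$delta_chi *
                             constants$b0))
  out <- scale * (dr2star_peak / dr2_peak)^(3 / 2)
  out[!is.finite(out) | dr2_peak <= 0 | dr2star_peak <= 0] <- NA_real_
  out
}

#' Bolus integral and relative cerebral blood volume
#'
#' `bolus_integral()` is the trapezoidal integral of a
#' leakage-corrected dR2* curve over the post-baseline window.
#' `compute_rcbv()` divides it by a reference statistic (the
#' healthy-hemisphere whole-brain mean of the same integral), so that
#' the healthy-hemisphere mean rCBV is 1 before any reporting scale.
#'
#' @param curve Leakage-corrected dR2* series, 1/s.
#' @param time Sample times, seconds.
#' @param n_baseline Number of baseline frames excluded from the
#'   integral.
#' @return `bolus_integral()`: the integral (dimensionless x 1/s x s).
#' @export
bolus_integral <- function(curve, time, n_baseline) {
  stopifnot(length(curve) == length(time), n_baseline < length(time))
  idx <- (n_baseline + 1):length(time)
  pracma::trapz(time[idx], curve[idx])
}

#' @rdname bolus_integral
#' @param reference_stat Positive normalizing constant.
#' @return `compute_rcbv()`: the normalized value; negative integrals
#'   give `NA`.
#' @export
compute_rcbv <- function(curve, time, n_baseline, reference_stat = 1) {
  stopifnot(reference_stat > 0)
  val <- bolus_integral(curve, time, n_baseline) / reference_stat
  if (!is.finite(val) || val < 0) return(NA_real_)
  val
}

#' Hemisphere specification
#'
#' Identifies the lesioned hemisphere and the midline along the first
#' array dimension of the grid; the healthy hemisphere is the
#' complement.
#'
#' @param lesion_side `"left"` or `"right"`.
#' @param nx Grid extent along the left-right axis.
#' @param midline Column index of the last left-hemisphere slice
#'   (default `nx / 2`).
#' @return A `vam_hemisphere` list with a logical `lesion_cols` mask
#'   over columns.
#' @export
hemisphere_spec <- function(lesion_side, nx, midline = nx %/% 2) {
  lesion_side <- match.arg(lesion_side, c("left", "right"))
  cols <- seq_len(nx)
  lesion_cols <- if (lesion_side == "left") cols <= midline else cols > midline
  structure(list(lesion_side = lesion_side, nx = as.integer(nx),
                 midline = as.integer(midline),
                 lesion_cols = lesion_cols),
            class = "vam_hemisphere")
}

vam_parameter_names <- function() {
  c("i", "vti", "vips", "cgi", "cbi", "bvf", "vsi", "q", "rcbv")
}

#' Assemble the nine whole-volume parameter maps
#'
#' Places per-voxel parameter values into 3D arrays on the mask grid:
#' `NA` outside the brain mask and at voxels whose fits were invalid,
#' and exactly zero throughout the lesioned hemisphere.
#'
#' @param params A tibble with a `voxel` column of linear indices into
#'   the mask grid plus one column per parameter in
#'   `vam_parameter_names()`.
#' @param mask 3D array; voxels with value > 0 form the brain mask.
#' @param hemisphere A [hemisphere_spec()] matching `dim(mask)[1]`.
#' @return Named list of nine 3D arrays (class `vam_maps`).
#' @export
assemble_maps <- function(params, mask, hemisphere) {
  stopifnot(inherits(hemisphere, "vam_hemisphere"),
            dim(mask)[1] == hemisphere$nx,
            all(vam_parameter_names() %in% names(params)))
  if (any(params$voxel < 1 | params$voxel > length(mask)))
    stop("voxel index outside the mask grid")
  dims <- dim(mask)
  lesion_vox <- array(rep(hemisphere$lesion_cols,
                          times = prod(dims[2:3])), dim = dims)
  maps <- lapply(vam_parameter_names(), function(pn) {
    m <- array(NA_real_, dim = dims)
    m[params$voxel] <- params[[pn]]
    m[as.integer(mask) == 0L] <- NA_real_
    m[lesion_vox] <- 0
    m
  })
  names(maps) <- vam_parameter_names()
  structure(maps, class = "vam_maps")
}

#' Write parameter maps as NIfTI with a JSON sidecar
#'
#' One `<subject>_<param>.nii.gz` per map plus a sidecar JSON recording
#' the physical constants, units, and package version.
#'
#' @param maps A `vam_maps` list from [assemble_maps()].
#' @param dir Output directory.
#' @param subject_id Subject identifier used in file names.
#' @param constants The [physical_constants()] used.
#' @return Invisibly, the paths written.
#' @export
write_parameter_maps <- function(maps, dir, subject_id = "sub-01",
                                 constants = physical_constants()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (pn in names(maps)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", subject_id, pn))
    RNifti::writeNifti(maps[[pn]], p)
    paths <- c(paths, p)
  }
  side <- file.path(dir, sprintf("%s_maps.json", subject_id))
  jsonlite::write_json(
    list(subject_id = subject_id,
         parameters = names(maps),
         units = list(i = "1/s", vti = "1/s^2", vips = "s", cgi = "",
                      cbi = "1/s", bvf = "1/s", vsi = "um",
                      q = "s^(-1/3)", rcbv = ""),
         constants = unclass(constants),
         software = paste0("vamkit ",
                           as.character(utils::packageVersion("vamkit")))),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read parameter maps written by [write_parameter_maps()]
#'
#' @param dir Directory containing the maps.
#' @param subject_id Subject identifier.
#' @return A `vam_maps` list of 3D arrays.
#' @export
read_parameter_maps <- function(dir, subject_id = "sub-01") {
  maps <- lapply(vam_parameter_names(), function(pn) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", subject_id, pn))
    arr <- RNifti::readNifti(p)
    array(as.numeric(arr), dim = dim(arr))
  })
  names(maps) <- vam_parameter_names()
  structure(maps, class = "vam_maps")
}
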