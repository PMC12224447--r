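#' Ground-truth vascular parameters for one simulated voxel
#'
#' Describes the noiseless physics of a single voxel during bolus
#' passage: peak relaxation-rate changes and times-to-peak for each
#' echo, the gamma-variate shape, optional contrast-leakage terms, the
#' baseline signals, and the additive noise level. The gamma-variate is
#' parameterized by (peak amplitude, time-to-peak, shape `alpha`); the
#' scale `beta` is derived from `ttp = t0 + alpha * beta` so the
#' parameters are non-redundant.
#'
#' @param amplitude_ge,amplitude_se Peak relaxation-rate change of the
#'   gradient-echo (dR2*) and spin-echo (dR2) curves, 1/s, >= 0.
#' @param ttp_ge,ttp_se True time-to-peak of each curve, seconds.
#' @param alpha Gamma-variate shape parameter (> 0), shared by both
#'   echoes.
#' @param t0 Bolus arrival time, seconds; defaults to the end of a 15 s
#'   baseline.
#' @param leak_k1 Dimensionless scaling applied to the voxel's
#'   intravascular gradient-echo curve when leakage is simulated.
#' @param leak_k2 Leakage rate, 1/s. When nonzero the gradient-echo
#'   curve acquires an extravasation term proportional to the running
#'   integral of a supplied reference curve.
#' @param s0_ge,s0_se Baseline signal intensities, arbitrary units, > 0.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   magnitude signal, arbitrary units, >= 0.
#'
#' @return A `vam_voxel_truth` list.
#' @seealso [simulate_voxel()]
#' @export
voxel_truth <- function(amplitude_ge, amplitude_se, ttp_ge, ttp_se,
                        alpha = 3, t0 = 15,
                        leak_k1 = 1, leak_k2 = 0,
                        s0_ge = 1000, s0_se = 800, noise_sd = 0) {
  stopifnot(amplitude_ge >= 0, amplitude_se >= 0,
            alpha > 0, noise_sd >= 0, t0 >= 0)
  if (amplitude_ge > 0 && ttp_ge <= t0)
    stop("ttp_ge must exceed the bolus arrival time t0")
  if (amplitude_se > 0 && ttp_se <= t0)
    stop("ttp_se must exceed the bolus arrival time t0")
  structure(
    list(amplitude_ge = amplitude_ge, amplitude_se = amplitude_se,
         ttp_ge = ttp_ge, ttp_se = ttp_se, alpha = alpha, t0 = t0,
         beta_ge = if (amplitude_ge > 0) (ttp_ge - t0) / alpha else NA_real_,
         beta_se = if (amplitude_se > 0) (ttp_se - t0) / alpha else NA_real_,
         leak_k1 = leak_k1, leak_k2 = leak_k2,
         s0_ge = s0_ge, s0_se = s0_se, noise_sd = noise_sd),
    class = "vam_voxel_truth"
  )
}

# Noiseless relaxation-rate curves implied by a voxel truth.
truth_delta_r <- function(truth, time, reference_curve = NULL) {
  dr_ge <- if (truth$amplitude_ge > 0) {
    gamma_variate(time,
                  gamma_scale_for_peak(truth$amplitude_ge, truth$alpha,
                                       truth$beta_ge),
                  truth$t0, truth$alpha, truth$beta_ge)
  } else numeric(length(time))
  dr_se <- if (truth$amplitude_se > 0) {
    gamma_variate(time,
                  gamma_scale_for_peak(truth$amplitude_se, truth$alpha,
                                       truth$beta_se),
                  truth$t0, truth$alpha, truth$beta_se)
  } else numeric(length(time))
  if (truth$leak_k2 != 0) {
    if (is.null(reference_curve))
      stop("leak_k2 != 0 requires a reference_curve")
    stopifnot(length(reference_curve) == length(time))
    dr_ge <- truth$leak_k1 * dr_ge -
      truth$leak_k2 * pracma::cumtrapz(time, reference_curve)[, 1]
  }
  list(ge = dr_ge, se = dr_se)
}

#' Simulate one voxel's dual-echo bolus-passage signal
#'
#' Forward model of the relaxometry: the voxel's true relaxation-rate
#' change curves are gamma-variates (plus an optional leakage term on
#' the gradient echo), converted to magnitude signals via
#' `S(t) = S0 * exp(-TE * dR(t))`, with additive Gaussian noise.
#'
#' @param truth A [voxel_truth()].
#' @param acq An [acquisition_params()].
#' @param reference_curve Optional sampled reference dR2* curve (1/s, on
#'   `acq$time`) whose running integral drives the leakage term; required
#'   when `truth$leak_k2` is nonzero.
#'
#' @return A `vam_voxel_sim` list with `signal_ge`, `signal_se` (length
#'   `acq$n_frames`), the noiseless generating curves `dr_ge_true`,
#'   `dr_se_true`, and the inputs.
#' @examples
#' acq <- acquisition_params()
#' v <- voxel_truth(amplitude_ge = 25, amplitude_se = 3.5,
#'                  ttp_ge = 21, ttp_se = 20.6)
#' sim <- simulate_voxel(v, acq)
#' @export
simulate_voxel <- function(truth, acq, reference_curve = NULL) {
  stopifnot(inherits(truth, "vam_voxel_truth"), inherits(acq, "vam_acq"))
  if (truth$s0_ge <= 0 || truth$s0_se <= 0)
    stop("baseline signal S0 must be positive")
  last_t <- max(acq$time)
  if ((truth$amplitude_ge > 0 && truth$ttp_ge > last_t) ||
      (truth$amplitude_se > 0 && truth$ttp_se > last_t))
    stop("time-to-peak lies outside the acquisition window")
  dr <- truth_delta_r(truth, acq$time, reference_curve)
  att_ge <- exp(-acq$te_ge * dr$ge)
  att_se <- exp(-acq$te_se * dr$se)
  if (any(att_ge < 1e-12) || any(att_se < 1e-12))
    stop("relaxation-rate change too large: signal underflows to zero; ",
         "max TE*dR = ",
         signif(max(acq$te_ge * dr$ge, acq$te_se * dr$se), 3))
  sig_ge <- truth$s0_ge * att_ge
  sig_se <- truth$s0_se * att_se
  if (truth$noise_sd > 0) {
    sig_ge <- sig_ge + rnorm(length(sig_ge), sd = truth$noise_sd)
    sig_se <- sig_se + rnorm(length(sig_se), sd = truth$noise_sd)
  }
  structure(
    list(signal_ge = sig_ge, signal_se = sig_se,
         dr_ge_true = dr$ge, dr_se_true = dr$se,
         truth = truth, acq = acq),
    class = "vam_voxel_sim"
  )
}

#' Default volume-of-interest geometry for the simulation grid
#'
#' Places eight disjoint box-shaped VOIs (labelled 1-8, named after the
#' eight analyzed brain regions) inside one hemisphere of the simulation
#' grid. The midline splits the first array dimension in half; the
#' healthy hemisphere is the side opposite the lesion.
#'
#' @param grid_dim Integer vector of length 3, the simulation grid.
#' @param healthy_side `"left"` or `"right"`: hemisphere that carries
#'   the VOIs.
#' @return Integer 3D array of region labels (0 = background).
#' @export
voi_geometry <- function(grid_dim = c(24, 24, 6), healthy_side = "right") {
  stopifnot(length(grid_dim) == 3, all(grid_dim >= c(18, 21, 4)))
  healthy_side <- match.arg(healthy_side, c("left", "right"))
  nx <- grid_dim[1]
  mask <- array(0L, dim = grid_dim)
  half <- nx %/% 2
  # 8 boxes of 3 x 3 x 2 voxels in the right half, mirrored if needed
  x_starts <- half + c(2L, 2L, 2L, 2L, 7L, 7L, 7L, 7L)
  y_starts <- rep(c(3L, 8L, 13L, 18L), 2)
  z0 <- max(1L, grid_dim[3] %/% 2 - 1L)
  for (lab in 1:8) {
    xs <- x_starts[lab] + 0:2
    ys <- y_starts[lab] + 0:2
    zs <- z0 + 0:1
    if (healthy_side == "left") xs <- nx + 1L - xs
    mask[xs, ys, zs] <- lab
  }
  attr(mask, "region_names") <- vam_region_names()
  mask
}

vam_region_names <- function() {
  c("cGM", "WM", "caudate_nucleus", "putamen",
    "globus_pallidus", "thalamus", "insula", "hippocampus")
}

#' Simulate one subject's dual-echo 4D series
#'
#' Builds a small 3D grid with labelled VOIs in the healthy hemisphere,
#' gives every voxel of a region that region's ground-truth parameters,
#' and generates the paired gradient-echo/spin-echo 4D signal arrays
#' with additive Gaussian noise. Background voxels carry constant
#' baseline signal.
#'
#' @param truths Named list of [voxel_truth()] objects, one per region
#'   label name present in the mask (names matching
#'   `attr(mask, "region_names")`, or `"1"`, `"2"`, ... for unnamed
#'   masks).
#' @param acq An [acquisition_params()].
#' @param mask Integer 3D label array; defaults to [voi_geometry()] on
#'   the healthy side.
#' @param grid_dim Grid used when `mask` is NULL.
#' @param lesion_side `"left"` or `"right"`; VOIs are placed on the
#'   opposite (healthy) side.
#' @param subject_id Identifier stored with the output.
#'
#' @return A `vam_subject` list: `signal_ge`, `signal_se` (4D arrays),
#'   `mask` (3D integer array), `truths`, `acq`, `lesion_side`,
#'   `subject_id`.
#' @export
simulate_subject <- function(truths, acq, mask = NULL,
                             grid_dim = c(24, 24, 6),
                             lesion_side = "left",
                             subject_id = "sub-01") {
  stopifnot(inherits(acq, "vam_acq"))
  lesion_side <- match.arg(lesion_side, c("left", "right"))
  healthy <- if (lesion_side == "left") "right" else "left"
  if (is.null(mask)) mask <- voi_geometry(grid_dim, healthy)
  labels <- sort(setdiff(unique(as.integer(mask)), 0L))
  rnames <- attr(mask, "region_names")
  if (is.null(rnames)) rnames <- as.character(labels)
  if (length(labels) < 1) stop("mask contains no labelled regions")
  need <- rnames[labels]
  missing_regions <- setdiff(need, names(truths))
  if (length(missing_regions))
    stop("no voxel truth for region(s): ",
         paste(missing_regions, collapse = ", "))

  dims <- dim(mask)
  nt <- acq$n_frames
  nvox <- prod(dims)

  # background: constant baseline signal
  bg <- truths[[need[1]]]
  flat_ge <- matrix(bg$s0_ge, nrow = nvox, ncol = nt)
  flat_se <- matrix(bg$s0_se, nrow = nvox, ncol = nt)

  noise_sd <- 0
  for (lab in labels) {
    tr <- truths[[rnames[lab]]]
    dr <- truth_delta_r(tr, acq$time)
    idx <- which(as.integer(mask) == lab)
    flat_ge[idx, ] <- rep(tr$s0_ge * exp(-acq$te_ge * dr$ge),
                          each = length(idx))
    flat_se[idx, ] <- rep(tr$s0_se * exp(-acq$te_se * dr$se),
                          each = length(idx))
    noise_sd <- max(noise_sd, tr$noise_sd)
  }
  if (noise_sd > 0) {
    flat_ge <- flat_ge + rnorm(length(flat_ge), sd = noise_sd)
    flat_se <- flat_se + rnorm(length(flat_se), sd = noise_sd)
  }
  sig_ge <- array(flat_ge, dim = c(dims, nt))
  sig_se <- array(flat_se, dim = c(dims, nt))
  structure(
    list(signal_ge = sig_ge, signal_se = sig_se, mask = mask,
         truths = truths, acq = acq, lesion_side = lesion_side,
         subject_id = subject_id),
    class = "vam_subject"
  )
}

#' Region-level default truths for a synthetic healthy hemisphere
#'
#' Baseline vascular parameters per region, chosen so that the derived
#' quantities land in the physiological ranges of healthy adult brain:
#' gradient-echo peak dR2* of 18-30 1/s, spin-echo peak dR2 of
#' 3-4.5 1/s, and a spin-echo lead of 0.2-0.6 s over the gradient echo
#' (so loops run counterclockwise and I, VTI, VIPS are negative, as in
#' healthy tissue).
#'
#' @param noise_sd Additive signal noise SD passed to every region.
#' @return Named list of [voxel_truth()] objects for the 8 regions.
#' @export
region_truth_defaults <- function(noise_sd = 5) {
  base <- list(
    #            amp_ge amp_se  vips
    cGM             = c(26, 4.2, -0.45),
    WM              = c(18, 3.6, -0.35),
    caudate_nucleus = c(27, 3.6, -0.40),
    putamen         = c(20, 4.6, -0.25),
    globus_pallidus = c(17, 4.8, -0.20),
    thalamus        = c(24, 4.1, -0.30),
    insula          = c(28, 4.0, -0.25),
    hippocampus     = c(28, 3.8, -0.45)
  )
  ttp_ge <- 21
  lapply(base, function(b) {
    voxel_truth(amplitude_ge = b[1], amplitude_se = b[2],
                ttp_ge = ttp_ge, ttp_se = ttp_ge + b[3],
                noise_sd = noise_sd)
  })
}

#' Planted covariate effect on a ground-truth field
#'
#' Describes a linear age effect on one [voxel_truth()] field, applied
#' to a subset of regions and sexes when simulating a cohort. Relative
#' effects multiply the base value by
#' `1 + slope_per_decade * (age - reference_age) / 10`.
#'
#' @param field One of `"amplitude_ge"`, `"amplitude_se"`, `"ttp_se"`,
#'   `"ttp_ge"` (for `"ttp_se"`/`"ttp_ge"`, the effect is additive in
#'   seconds regardless of `relative`).
#' @param regions Character vector of region names, or `"all"`.
#' @param sex Sexes the effect applies to, subset of `c("F", "M")`.
#' @param slope_per_decade Effect size per decade of age (relative
#'   fraction for amplitudes, seconds for times).
#' @param reference_age Age (years) at which the effect is zero.
#' @return A `vam_effect` list.
#' @export
cohort_effect <- function(field, regions = "all", sex = c("F", "M"),
                          slope_per_decade = 0.05, reference_age = 40) {
  field <- match.arg(field, c("amplitude_ge", "amplitude_se",
                              "ttp_se", "ttp_ge"))
  stopifnot(all(sex %in% c("F", "M")), length(sex) >= 1)
  structure(list(field = field, regions = regions, sex = sex,
                 slope_per_decade = slope_per_decade,
                 reference_age = reference_age),
            class = "vam_effect")
}

#' Specification of a synthetic cohort
#'
#' Cohort-level layout mirroring the study design this package
#' validates against: 42 women and 30 men aged 20-70 years, BMI drawn
#' per sex (women: mean 24.8, SD 4.2, no age trend; men: mean 26.3,
#' SD 3.2 with a positive age slope), lesion hemispheres balanced
#' left/right, and an optional list of planted [cohort_effect()]s on the
#' underlying vascular truth. Between-subject biological variability is
#' lognormal on the amplitudes (coefficient of variation
#' `subject_cv`) and Gaussian on the SE-GE peak-time offset
#' (`ttp_jitter_sd`, seconds).
#'
#' @param n_female,n_male Subject counts per sex.
#' @param age_range Years, length-2 vector; ages drawn uniformly.
#' @param effects List of [cohort_effect()] objects (possibly empty).
#' @param grid_dim Simulation grid per subject.
#' @param noise_sd Additive signal noise SD.
#' @param subject_cv Between-subject CV of the amplitude fields.
#' @param ttp_jitter_sd Between-subject SD of the SE-GE lag, seconds.
#' @param seed Integer seed making the cohort reproducible.
#' @return A `vam_cohort_spec` list.
#' @export
cohort_spec <- function(n_female = 42, n_male = 30,
                        age_range = c(20, 70),
                        effects = list(),
                        grid_dim = c(24, 24, 6),
                        noise_sd = 5,
                        subject_cv = 0.08,
                        ttp_jitter_sd = 0.08,
                        seed = 1) {
  stopifnot(n_female >= 0, n_male >= 0, n_female + n_male > 0,
            length(age_range) == 2, age_range[1] < age_range[2])
  for (e in effects) {
    if (!inherits(e, "vam_effect")) stop("effects must be cohort_effect()s")
    bad <- setdiff(setdiff(e$regions, "all"), vam_region_names())
    if (length(bad)) stop("effect references unknown region: ",
                          paste(bad, collapse = ", "))
    if (("F" %in% e$sex && n_female == 0) ||
        ("M" %in% e$sex && n_male == 0))
      stop("effect references an empty sex stratum")
  }
  structure(list(n_female = n_female, n_male = n_male,
                 age_range = age_range, effects = effects,
                 grid_dim = grid_dim, noise_sd = noise_sd,
                 subject_cv = subject_cv, ttp_jitter_sd = ttp_jitter_sd,
                 seed = as.integer(seed)),
            class = "vam_cohort_spec")
}

# BMI model defaults: women flat in age; men gain ~1.3 kg/m2 per decade
# (residual SD shrunk so the marginal SD matches the stated 3.2).
draw_bmi <- function(sex, age) {
  if (sex == "F") {
    24.8 + rnorm(1, sd = 4.2)
  } else {
    26.3 + 1.34 * (age - 40) / 10 + rnorm(1, sd = 2.74)
  }
}

apply_effects <- function(truth, region, sex, age, effects) {
  for (e in effects) {
    if (!(sex %in% e$sex)) next
    if (!identical(e$regions, "all") && !(region %in% e$regions)) next
    shift <- e$slope_per_decade * (age - e$reference_age) / 10
    if (e$field %in% c("amplitude_ge", "amplitude_se")) {
      truth[[e$field]] <- max(truth[[e$field]] * (1 + shift), 1e-6)
    } else {
      truth[[e$field]] <- truth[[e$field]] + shift
    }
  }
  truth
}

#' Simulate a whole synthetic cohort
#'
#' Draws demographics per [cohort_spec()], resolves per-subject,
#' per-region ground truths (baseline region values, planted effects,
#' between-subject variability), and simulates every subject's 4D
#' dual-echo series with [simulate_subject()]. Fully reproducible for a
#' fixed spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @param acq An [acquisition_params()].
#' @return A `vam_cohort` list with `subjects` (list of `vam_subject`),
#'   `demographics` (tibble: subject_id, age_years, sex, bmi,
#'   lesion_hemisphere), `truth` (tibble of resolved per-subject,
#'   per-region truth fields), and `spec`.
#' @examples
#' \donttest{
#' spec <- cohort_spec(n_female = 3, n_male = 2, grid_dim = c(18, 22, 4))
#' coh <- simulate_cohort(spec, acquisition_params())
#' coh$demographics
#' }
#' @export
simulate_cohort <- function(spec, acq = acquisition_params()) {
  stopifnot(inherits(spec, "vam_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_female + spec$n_male
  sexes <- c(rep("F", spec$n_female), rep("M", spec$n_male))
  ages <- runif(n, spec$age_range[1], spec$age_range[2])
  lesions <- rep(c("left", "right"), length.out = n)
  base <- region_truth_defaults(noise_sd = spec$noise_sd)

  subjects <- vector("list", n)
  sids <- sprintf("sub-%03d", seq_len(n))
  bmis <- numeric(n)
  tr_sid <- character(0); tr_region <- character(0)
  tr_mat <- matrix(numeric(0), ncol = 4)
  for (i in seq_len(n)) {
    bmis[i] <- draw_bmi(sexes[i], ages[i])
    truths <- base
    for (rn in names(truths)) {
      tr <- truths[[rn]]
      tr <- apply_effects(tr, rn, sexes[i], ages[i], spec$effects)
      # between-subject biological variability
      tr$amplitude_ge <- tr$amplitude_ge *
        exp(rnorm(1, sd = spec$subject_cv))
      tr$amplitude_se <- tr$amplitude_se *
        exp(rnorm(1, sd = spec$subject_cv))
      tr$ttp_se <- tr$ttp_se + rnorm(1, sd = spec$ttp_jitter_sd)
      truths[[rn]] <- voxel_truth(
        amplitude_ge = tr$amplitude_ge, amplitude_se = tr$amplitude_se,
        ttp_ge = tr$ttp_ge, ttp_se = tr$ttp_se, alpha = tr$alpha,
        t0 = tr$t0, leak_k1 = tr$leak_k1, leak_k2 = tr$leak_k2,
        s0_ge = tr$s0_ge, s0_se = tr$s0_se, noise_sd = tr$noise_sd)
      tr_sid <- c(tr_sid, sids[i]); tr_region <- c(tr_region, rn)
      tr_mat <- rbind(tr_mat, c(tr$amplitude_ge, tr$amplitude_se,
                                tr$ttp_ge, tr$ttp_se))
    }
    subjects[[i]] <- simulate_subject(truths, acq,
                                      grid_dim = spec$grid_dim,
                                      lesion_side = lesions[i],
                                      subject_id = sids[i])
  }
  structure(
    list(subjects = subjects,
         demographics = tibble(subject_id = sids, age_years = ages,
                               sex = sexes, bmi = bmis,
                               lesion_hemisphere = lesions),
         truth = tibble(subject_id = tr_sid, region = tr_region,
                        amplitude_ge = tr_mat[, 1],
                        amplitude_se = tr_mat[, 2],
                        ttp_ge = tr_mat[, 3], ttp_se = tr_mat[, 4],
                        vips_true = tr_mat[, 4] - tr_mat[, 3]),
         spec = spec),
    class = "vam_cohort"
  )
}

#' Write a simulated subject to disk (NIfTI + JSON)
#'
#' Writes one NIfTI-1 4D image per echo, the integer VOI label mask,
#' and the ground-truth record as JSON, into `dir`.
#'
#' @param subject A `vam_subject`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "vam_subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(subject$subject_id,
                                 c("_ge.nii.gz", "_se.nii.gz",
                                   "_mask.nii.gz", "_truth.json")))
  RNifti::writeNifti(subject$signal_ge, paths[1])
  RNifti::writeNifti(subject$signal_se, paths[2])
  mask <- subject$mask
  attributes(mask) <- list(dim = dim(mask))
  RNifti::writeNifti(mask, paths[3], datatype = "int16")
  truth <- lapply(subject$truths, function(tr) unclass(tr))
  jsonlite::write_json(
    list(subject_id = subject$subject_id,
         lesion_side = subject$lesion_side,
         acq = unclass(subject$acq)[c("tr", "te_ge", "te_se",
                                      "n_baseline", "n_frames")],
         truths = truth),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write cohort demographics to CSV
#'
#' @param cohort A `vam_cohort`.
#' @param path CSV file path.
#' @return Invisibly, `path`.
#' @export
write_demographics <- function(cohort, path) {
  stopifnot(inherits(cohort, "vam_cohort"))
  write.csv(cohort$demographics, path, row.names = FALSE)
  invisible(path)
}
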