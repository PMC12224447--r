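# End-to-end orchestration: signals -> relaxometry -> loop geometry ->
# parameter maps -> VOI means -> cohort statistics.

# Leakage-correct many voxels at once against a common reference.
leakage_correct_batch <- function(dr_ge, reference, time) {
  cum_ref <- pracma::cumtrapz(time, reference)[, 1]
  x <- cbind(reference, -cum_ref)
  xtx <- crossprod(x)
  coefs <- solve(xtx, crossprod(x, dr_ge))  # 2 x V
  k2 <- coefs[2, ]
  corrected <- dr_ge + cum_ref %o% k2
  list(corrected = corrected, k1 = coefs[1, ], k2 = k2)
}

# Minimal fit object for the batch path, compatible with the
# loop-geometry functions.
batch_fit_obj <- function(fit, v, time) {
  structure(list(a = fit$a[v], t0 = fit$t0[v], alpha = fit$alpha[v],
                 beta = fit$beta[v], ttp = fit$ttp[v],
                 peak = fit$peak[v], r2 = fit$r2[v],
                 valid = fit$valid[v], fitted = NULL, time = time),
            class = "vam_gamma_fit")
}

#' Run the full per-subject analysis
#'
#' Converts a subject's dual-echo 4D series to relaxation-rate curves,
#' applies the leakage correction to the gradient echo against the
#' whole-brain reference curve, fits gamma-variates per voxel (both
#' echoes), builds the hysteresis loop and its six parameters, computes
#' VSI, Q and rCBV, assembles the nine parameter maps (lesioned
#' hemisphere zeroed), and reduces them to VOI means.
#'
#' @param subject A `vam_subject` (from [simulate_subject()] or
#'   [read_subject()]).
#' @param constants A [physical_constants()].
#' @param peak_snr_min,r2_min Fit-quality gates (see
#'   [fit_gamma_variate()]).
#' @param oversample Loop sampling density (see [build_vortex_loop()]).
#' @return A `vam_subject_result`: `maps` (list of nine 3D arrays),
#'   `params` (per-voxel tibble), `voi_means` (tibble: one row per
#'   VOI x parameter), `log` (per-stage counters).
#' @export
run_subject <- function(subject, constants = physical_constants(),
                        peak_snr_min = 3, r2_min = 0.6, oversample = 4) {
  stopifnot(inherits(subject, "vam_subject"))
  acq <- subject$acq
  mask <- subject$mask
  if (!identical(dim(subject$signal_ge)[1:3], dim(mask)) ||
      !identical(dim(subject$signal_se)[1:3], dim(mask)))
    stop("signal and mask grids do not match")
  dims <- dim(mask)
  nt <- acq$n_frames
  hemi <- hemisphere_spec(subject$lesion_side, dims[1])
  lesion_vox <- array(rep(hemi$lesion_cols, times = prod(dims[2:3])),
                      dim = dims)

  mask_idx <- which(as.integer(mask) > 0L & !lesion_vox)
  nv <- length(mask_idx)
  if (nv == 0) stop("no brain voxels in the healthy hemisphere")

  flat_ge <- matrix(subject$signal_ge, nrow = prod(dims), ncol = nt)
  flat_se <- matrix(subject$signal_se, nrow = prod(dims), ncol = nt)
  y_ge <- t(flat_ge[mask_idx, , drop = FALSE])
  y_se <- t(flat_se[mask_idx, , drop = FALSE])

  nb <- acq$n_baseline
  s0_ge <- colMeans(y_ge[seq_len(nb), , drop = FALSE])
  s0_se <- colMeans(y_se[seq_len(nb), , drop = FALSE])
  sig_ok <- s0_ge > 0 & s0_se > 0 &
    apply(y_ge > 0, 2, all) & apply(y_se > 0, 2, all)

  dr_ge <- matrix(NA_real_, nt, nv)
  dr_se <- matrix(NA_real_, nt, nv)
  ok <- which(sig_ok)
  dr_ge[, ok] <- -(1 / acq$te_ge) *
    log(sweep(y_ge[, ok, drop = FALSE], 2, s0_ge[ok], "/"))
  dr_se[, ok] <- -(1 / acq$te_se) *
    log(sweep(y_se[, ok, drop = FALSE], 2, s0_se[ok], "/"))

  # whole-brain (healthy hemisphere) reference and leakage correction
  reference <- rowMeans(dr_ge[, ok, drop = FALSE])
  lk <- leakage_correct_batch(dr_ge[, ok, drop = FALSE], reference,
                              acq$time)
  dr_ge_corr <- dr_ge
  dr_ge_corr[, ok] <- lk$corrected

  fit_zero <- list(a = rep(NA_real_, nv), t0 = rep(NA_real_, nv),
                   alpha = rep(NA_real_, nv), beta = rep(NA_real_, nv),
                   ttp = rep(NA_real_, nv), peak = rep(NA_real_, nv),
                   r2 = rep(NA_real_, nv), valid = rep(FALSE, nv))
  fill_fit <- function(skel, fit, ok) {
    for (f in names(skel)) skel[[f]][ok] <- fit[[f]]
    skel
  }
  fit_ge <- fit_zero; fit_se <- fit_zero
  if (length(ok)) {
    fit_ge <- fill_fit(fit_ge,
                       fit_gamma_batch(dr_ge_corr[, ok, drop = FALSE],
                                       acq$time, nb, peak_snr_min, r2_min),
                       ok)
    fit_se <- fill_fit(fit_se,
                       fit_gamma_batch(dr_se[, ok, drop = FALSE],
                                       acq$time, nb, peak_snr_min, r2_min),
                       ok)
  }
  both_valid <- fit_ge$valid & fit_se$valid

  # loop geometry per voxel
  vhl <- matrix(NA_real_, nv, 7,
                dimnames = list(NULL, c("i", "vti", "vips", "cgi", "cbi",
                                        "bvf", "orientation")))
  for (v in which(both_valid)) {
    vhl[v, ] <- vhl_numbers(batch_fit_obj(fit_se, v, acq$time),
                            batch_fit_obj(fit_ge, v, acq$time),
                            oversample = oversample)
  }

  # VSI, Q from fitted peaks; rCBV from corrected GE integral
  vsi <- compute_vsi(fit_ge$peak, fit_se$peak, constants)
  qd <- compute_q(fit_se$peak, fit_ge$peak)
  dt_w <- diff(acq$time[(nb + 1):nt])
  w <- c(dt_w / 2, 0) + c(0, dt_w / 2)  # trapezoid weights
  integral <- rep(NA_real_, nv)
  integral[ok] <- colSums(dr_ge_corr[(nb + 1):nt, ok, drop = FALSE] * w)
  ref_stat <- mean(integral[both_valid], na.rm = TRUE)
  rcbv <- integral / ref_stat
  rcbv[!is.finite(rcbv) | rcbv < 0] <- NA_real_

  params <- tibble(
    voxel = mask_idx,
    i = vhl[, "i"], vti = vhl[, "vti"], vips = vhl[, "vips"],
    cgi = vhl[, "cgi"], cbi = vhl[, "cbi"], bvf = vhl[, "bvf"],
    vsi = vsi, q = qd, rcbv = rcbv,
    orientation = vhl[, "orientation"],
    valid = both_valid)
  # missing-value closure: no parameter for voxels with an invalid fit
  for (pn in vam_parameter_names()) params[[pn]][!both_valid] <- NA_real_

  maps <- assemble_maps(params, mask, hemi)

  rnames <- attr(mask, "region_names")
  labels <- sort(setdiff(unique(as.integer(mask)), 0L))
  pnames <- vam_parameter_names()
  grid_voi <- expand.grid(lab = labels, pn = pnames,
                          stringsAsFactors = FALSE)
  voi_stats <- matrix(NA_real_, nrow(grid_voi), 5)
  keep_row <- logical(nrow(grid_voi))
  for (r in seq_len(nrow(grid_voi))) {
    vm <- voi_mean_num(maps[[grid_voi$pn[r]]], mask, grid_voi$lab[r],
                       exclude = lesion_vox)
    if (vm[["n_voxels"]] == 0) next
    keep_row[r] <- TRUE
    voi_stats[r, ] <- vm
  }
  voi_means <- tibble(
    subject_id = subject$subject_id,
    voi_label = if (!is.null(rnames)) rnames[grid_voi$lab]
                else as.character(grid_voi$lab),
    parameter = grid_voi$pn,
    mean_value = voi_stats[, 1], sd_value = voi_stats[, 2],
    ci_lo = voi_stats[, 3], ci_hi = voi_stats[, 4],
    n_voxels = as.integer(voi_stats[, 5]))[keep_row, ]
  voi_means <- dplyr::arrange(voi_means, .data$voi_label,
                              .data$parameter)
  structure(
    list(maps = maps, params = params,
         voi_means = voi_means,
         log = list(n_mask_voxels = nv,
                    n_signal_valid = sum(sig_ok),
                    n_fit_ge_valid = sum(fit_ge$valid),
                    n_fit_se_valid = sum(fit_se$valid),
                    n_both_valid = sum(both_valid),
                    n_degenerate_loops =
                      sum(vhl[, "orientation"] == 0, na.rm = TRUE)),
         subject_id = subject$subject_id),
    class = "vam_subject_result"
  )
}

#' Read a subject written by [write_subject()]
#'
#' @param dir Directory holding `<id>_ge.nii.gz`, `<id>_se.nii.gz`,
#'   `<id>_mask.nii.gz` and `<id>_truth.json`.
#' @param subject_id Subject identifier.
#' @return A `vam_subject`.
#' @export
read_subject <- function(dir, subject_id) {
  pth <- function(sfx) file.path(dir, paste0(subject_id, sfx))
  meta <- jsonlite::read_json(pth("_truth.json"), simplifyVector = TRUE)
  acq <- acquisition_params(tr = meta$acq$tr, te_ge = meta$acq$te_ge,
                            te_se = meta$acq$te_se,
                            n_baseline = meta$acq$n_baseline,
                            n_frames = meta$acq$n_frames)
  ge <- RNifti::readNifti(pth("_ge.nii.gz"))
  se <- RNifti::readNifti(pth("_se.nii.gz"))
  mk <- RNifti::readNifti(pth("_mask.nii.gz"))
  mask <- array(as.integer(mk), dim = dim(mk))
  attr(mask, "region_names") <- vam_region_names()
  truths <- lapply(meta$truths, function(tr) {
    structure(tr, class = "vam_voxel_truth")
  })
  structure(
    list(signal_ge = array(as.numeric(ge), dim = dim(ge)),
         signal_se = array(as.numeric(se), dim = dim(se)),
         mask = mask, truths = truths, acq = acq,
         lesion_side = meta$lesion_side, subject_id = meta$subject_id),
    class = "vam_subject"
  )
}

#' Run the cohort pipeline and statistical battery
#'
#' Runs [run_subject()] on every subject, joins the VOI means to the
#' demographics into a cohort table (one row per subject x VOI x
#' parameter), screens each (VOI, parameter) column for outliers with
#' [rout_outliers()], and runs the battery: normality-gated sex
#' comparisons (t-test or Mann-Whitney) with Benjamini-Hochberg FDR
#' adjustment within each parameter across VOIs, and normality-gated
#' partial correlations of each column with age controlling for BMI
#' (unadjusted by default, adjustable via `adjust_correlations`).
#'
#' @param cohort A `vam_cohort` from [simulate_cohort()], or a list
#'   with `subjects` and `demographics` of the same shape.
#' @param constants A [physical_constants()].
#' @param rout_q ROUT outlier FDR level (default 0.01).
#' @param fdr_q FDR level of the Benjamini-Hochberg adjustment.
#' @param alpha Normality-gate level.
#' @param adjust_correlations If `TRUE`, BH-adjust the age
#'   correlations within each parameter as well.
#' @param sex_stratified If `TRUE`, also compute age partial
#'   correlations separately within each sex.
#' @return A `vam_cohort_result`: `cohort_table` (with `outlier`
#'   flags), `sex_results`, `age_results` (StatResult tibbles with
#'   `parameter`, `voi_label` columns), and `log`.
#' @export
run_cohort <- function(cohort, constants = physical_constants(),
                       rout_q = 0.01, fdr_q = 0.05, alpha = 0.05,
                       adjust_correlations = FALSE,
                       sex_stratified = FALSE) {
  demo <- cohort$demographics
  results <- lapply(cohort$subjects, run_subject, constants = constants)
  tab <- dplyr::bind_rows(lapply(results, `[[`, "voi_means"))
  tab <- dplyr::left_join(tab, demo, by = "subject_id")

  tab <- tab |>
    dplyr::group_by(.data$voi_label, .data$parameter) |>
    dplyr::mutate(outlier = rout_outliers(.data$mean_value, q = rout_q)) |>
    dplyr::ungroup()

  cells <- dplyr::distinct(tab, .data$voi_label, .data$parameter)
  sex_rows <- list(); age_rows <- list()
  for (k in seq_len(nrow(cells))) {
    vl <- cells$voi_label[k]; pn <- cells$parameter[k]
    cell <- tab[tab$voi_label == vl & tab$parameter == pn &
                  !tab$outlier, ]
    id <- paste(pn, vl, sep = "|")
    sr <- two_group_compare(cell$mean_value[cell$sex == "F"],
                            cell$mean_value[cell$sex == "M"],
                            comparison_id = paste0(id, "|F_vs_M"),
                            alpha = alpha)
    if (nrow(sr)) sex_rows[[length(sex_rows) + 1L]] <-
      dplyr::mutate(sr, parameter = pn, voi_label = vl)
    strata <- list(all = cell)
    if (sex_stratified) {
      strata$F <- cell[cell$sex == "F", ]
      strata$M <- cell[cell$sex == "M", ]
    }
    for (sn in names(strata)) {
      cc <- strata[[sn]]
      ar <- partial_correlation(cc$age_years, cc$mean_value, cc$bmi,
                                comparison_id =
                                  paste0(id, "|age_given_bmi|", sn),
                                alpha = alpha)
      if (nrow(ar)) age_rows[[length(age_rows) + 1L]] <-
        dplyr::mutate(ar, parameter = pn, voi_label = vl, stratum = sn)
    }
  }
  sex_results <- dplyr::bind_rows(sex_rows)
  age_results <- dplyr::bind_rows(age_rows)

  # FDR families: within each parameter across VOIs
  if (nrow(sex_results)) {
    sex_results <- sex_results |>
      dplyr::group_by(.data$parameter) |>
      dplyr::mutate(q_value = bh_fdr(.data$p_value, fdr_q)$q_values) |>
      dplyr::ungroup()
  }
  if (nrow(age_results)) {
    if (adjust_correlations) {
      age_results <- age_results |>
        dplyr::group_by(.data$parameter, .data$stratum) |>
        dplyr::mutate(q_value = bh_fdr(.data$p_value, fdr_q)$q_values) |>
        dplyr::ungroup()
    } else {
      age_results$q_value <- age_results$p_value
    }
  }
  structure(
    list(cohort_table = tab, sex_results = sex_results,
         age_results = age_results,
         log = list(n_subjects = length(cohort$subjects),
                    n_rows = nrow(tab),
                    n_outliers = sum(tab$outlier),
                    fdr_q = fdr_q, rout_q = rout_q),
         subject_logs = lapply(results, `[[`, "log")),
    class = "vam_cohort_result"
  )
}

#' @export
print.vam_cohort_result <- function(x, ...) {
  cat(sprintf(
    "<vam_cohort_result> %d subjects, %d table rows (%d outliers flagged)\n",
    x$log$n_subjects, x$log$n_rows, x$log$n_outliers))
  cat(sprintf("  sex comparisons: %d (BH within parameter, Q = %g)\n",
              nrow(x$sex_results), x$log$fdr_q))
  cat(sprintf("  age partial correlations: %d\n", nrow(x$age_results)))
  invisible(x)
}

#' Tidy the cohort statistical results
#'
#' @param x A `vam_cohort_result`.
#' @param ... Unused.
#' @return One StatResult row per test, sex comparisons and age
#'   partial correlations stacked, with a `family` column.
#' @export
tidy.vam_cohort_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$sex_results, family = "sex_comparison"),
    dplyr::mutate(x$age_results, family = "age_partial_correlation"))
}

#' @rdname tidy.vam_cohort_result
#' @export
glance.vam_cohort_result <- function(x, ...) {
  tibble(n_subjects = x$log$n_subjects,
         n_rows = x$log$n_rows,
         n_outliers = x$log$n_outliers,
         n_sex_significant = sum(x$sex_results$q_value <= x$log$fdr_q,
                                 na.rm = TRUE),
         n_age_significant = sum(x$age_results$p_value < 0.05,
                                 na.rm = TRUE))
}

#' Heatmap of cohort test results
#'
#' @param object A `vam_cohort_result`.
#' @param which `"age"` (partial correlation r) or `"sex"` (group
#'   difference), tiles parameter x VOI, starred where the reported
#'   q-value is below the FDR level.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vam_cohort_result <- function(object, which = c("age", "sex"),
                                       ...) {
  which <- match.arg(which)
  df <- if (which == "age") {
    d <- object$age_results
    if ("stratum" %in% names(d)) d <- d[d$stratum == "all", ]
    d
  } else object$sex_results
  df$sig <- ifelse(df$q_value <= object$log$fdr_q, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$voi_label,
                                   y = .data$parameter,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (which == "age") "partial r" else
                    "difference (F - M)",
                  title = if (which == "age")
                    "Age association (partial correlation, BMI-adjusted)"
                  else "Sex difference by VOI and parameter") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}
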