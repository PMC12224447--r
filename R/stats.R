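# Cohort-level statistical battery: robust outlier screening,
# normality-gated tests and correlations, FDR control.

#' VOI summary of a parameter map
#'
#' Mean, SD, 95% confidence interval and voxel count of one labelled
#' volume of interest, over valid (non-missing, non-excluded) voxels
#' only.
#'
#' @param map 3D numeric parameter map.
#' @param mask 3D integer label array of the same dimensions.
#' @param label Region label to summarize.
#' @param exclude Optional logical array of voxels to drop (e.g. a
#'   zeroed lesion hemisphere).
#' @return A one-row tibble (`label`, `mean`, `sd`, `ci_lo`, `ci_hi`,
#'   `n_voxels`); zero rows if the VOI has no valid voxel.
#' @export
voi_mean <- function(map, mask, label, exclude = NULL) {
  v <- voi_mean_num(map, mask, label, exclude)
  if (v[["n_voxels"]] == 0) {
    return(tibble(label = integer(0), mean = numeric(0), sd = numeric(0),
                  ci_lo = numeric(0), ci_hi = numeric(0),
                  n_voxels = integer(0)))
  }
  tibble(label = as.integer(label), mean = v[["mean"]], sd = v[["sd"]],
         ci_lo = v[["ci_lo"]], ci_hi = v[["ci_hi"]],
         n_voxels = as.integer(v[["n_voxels"]]))
}

# numeric core: c(mean, sd, ci_lo, ci_hi, n_voxels)
voi_mean_num <- function(map, mask, label, exclude = NULL) {
  stopifnot(identical(dim(map), dim(mask)))
  sel <- as.integer(mask) == as.integer(label)
  if (!any(sel)) stop("label ", label, " not present in mask")
  if (!is.null(exclude)) sel <- sel & !as.logical(exclude)
  v <- map[sel]
  v <- v[is.finite(v)]
  n <- length(v)
  if (n == 0)
    return(c(mean = NA_real_, sd = NA_real_, ci_lo = NA_real_,
             ci_hi = NA_real_, n_voxels = 0))
  m <- mean(v)
  s <- if (n > 1) sd(v) else 0
  half <- if (n > 1) qt(0.975, n - 1) * s / sqrt(n) else 0
  c(mean = m, sd = s, ci_lo = m - half, ci_hi = m + half, n_voxels = n)
}

#' ROUT robust outlier screen
#'
#' Robust-regression-and-outlier-test on a single sample: a robust
#' location is fitted by iteratively reweighted least squares with
#' Lorentzian weights, the robust SD (RSDR) is taken from the 68.27th
#' percentile of absolute residuals with the small-sample correction
#' `n / (n - 1)`, and points are tested against t-based thresholds via
#' a step-up rule controlling the false discovery rate of outlier
#' calls at `q` (default 1%). At most 30% of the sample can be
#' flagged.
#'
#' @param values Numeric sample (one VOI-by-parameter column across
#'   subjects).
#' @param q FDR level for outlier calling, in (0, 0.5); default 0.01.
#' @return Logical vector of outlier flags (same length as `values`).
#'   Samples with fewer than 10 values are returned unflagged with a
#'   warning.
#' @export
rout_outliers <- function(values, q = 0.01) {
  stopifnot(q > 0, q < 0.5)
  n <- length(values)
  flags <- rep(FALSE, n)
  if (n < 10) {
    warning("fewer than 10 values: outlier screening skipped")
    return(flags)
  }
  ok <- is.finite(values)
  v <- values[ok]
  m <- length(v)
  mu <- median(v)
  rsdr <- 0
  for (it in 1:50) {
    resid <- v - mu
    rsdr <- unname(quantile(abs(resid), 0.6827, type = 7)) * m / (m - 1)
    if (rsdr <= .Machine$double.eps * max(1, abs(mu))) return(flags)
    w <- 1 / (1 + (resid / rsdr)^2)
    mu_new <- sum(w * v) / sum(w)
    if (abs(mu_new - mu) < 1e-12 * max(1, abs(mu))) { mu <- mu_new; break }
    mu <- mu_new
  }
  resid <- v - mu
  rsdr <- unname(quantile(abs(resid), 0.6827, type = 7)) * m / (m - 1)
  if (rsdr <= .Machine$double.eps * max(1, abs(mu))) return(flags)
  p <- 2 * pt(-abs(resid) / rsdr, df = m - 1)
  ord <- order(p)
  kmax <- floor(0.3 * m)
  k_star <- 0
  for (k in seq_len(kmax)) {
    if (p[ord[k]] <= q * k / m) k_star <- k
  }
  if (k_star > 0) {
    out_idx <- which(ok)[ord[seq_len(k_star)]]
    flags[out_idx] <- TRUE
  }
  flags
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into `K2 = Zs^2 + Zk^2`, referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x Numeric sample, n >= 8.
#' @return A list: `statistic` (K2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  if (sd(x) == 0) stop("zero-variance sample")
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970) transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  z_skew <- delta * asinh(y / a)

  # kurtosis: Anscombe & Glynn (1983) transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z_kurt <- ((1 - 2 / (9 * aa)) -
               ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

#' Normality gate
#'
#' Classifies a sample as `"gaussian"` iff the D'Agostino-Pearson
#' omnibus test does not reject at `alpha`. Samples below the test's
#' validity floor (n < 8) or with zero variance are classified
#' `"non_gaussian"` with a warning.
#'
#' @param x Numeric sample.
#' @param alpha Significance level of the gate (default 0.05).
#' @return `"gaussian"` or `"non_gaussian"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 8) {
    warning("n < 8: normality gate returns non_gaussian")
    return("non_gaussian")
  }
  if (sd(x) == 0) {
    warning("zero variance: normality gate returns non_gaussian")
    return("non_gaussian")
  }
  if (dagostino_pearson(x)$p_value >= alpha) "gaussian" else "non_gaussian"
}

stat_result_row <- function(comparison_id, test_name, statistic,
                            estimate, p_value, n_used) {
  tibble(comparison_id = comparison_id, test_name = test_name,
         statistic = statistic, estimate = estimate,
         p_value = p_value, q_value = NA_real_, n_used = n_used)
}

#' Normality-gated two-group comparison
#'
#' Unpaired two-sided t-test when both groups pass the normality gate,
#' Mann-Whitney otherwise (normal approximation with tie correction
#' when exactness is not available). The path taken is recorded in
#' `test_name`.
#'
#' @param values_a,values_b Numeric samples for the two groups.
#' @param comparison_id Identifier copied into the result row.
#' @param alpha Gate level.
#' @return A one-row tibble (see `StatResult` fields: `comparison_id`,
#'   `test_name`, `statistic`, `estimate` = difference a - b in
#'   location, `p_value`, `q_value` (NA until FDR adjustment),
#'   `n_used`), or zero rows if a group has fewer than 2 values.
#' @export
two_group_compare <- function(values_a, values_b,
                              comparison_id = "a_vs_b", alpha = 0.05) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    return(stat_result_row(character(0), character(0), numeric(0),
                           numeric(0), numeric(0), integer(0)))
  }
  gate_a <- suppressWarnings(normality_gate(a, alpha))
  gate_b <- suppressWarnings(normality_gate(b, alpha))
  if (gate_a == "gaussian" && gate_b == "gaussian") {
    ht <- t.test(a, b, var.equal = TRUE)
    stat_result_row(comparison_id, "t", unname(ht$statistic),
                    mean(a) - mean(b), ht$p.value,
                    length(a) + length(b))
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = NULL))
    stat_result_row(comparison_id, "mann_whitney", unname(ht$statistic),
                    median(a) - median(b), ht$p.value,
                    length(a) + length(b))
  }
}

#' Normality-gated correlation
#'
#' Pearson correlation when both variables pass the normality gate,
#' Spearman otherwise; two-sided p-value.
#'
#' @param x,y Paired numeric samples (n >= 4 complete pairs).
#' @param comparison_id Identifier copied into the result row.
#' @param alpha Gate level.
#' @return A one-row StatResult tibble (`estimate` = r); zero rows for
#'   degenerate input (zero variance or too few pairs).
#' @export
correlate_gated <- function(x, y, comparison_id = "x_vs_y",
                            alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4 || sd(x) == 0 || sd(y) == 0) {
    return(stat_result_row(character(0), character(0), numeric(0),
                           numeric(0), numeric(0), integer(0)))
  }
  gate_x <- suppressWarnings(normality_gate(x, alpha))
  gate_y <- suppressWarnings(normality_gate(y, alpha))
  method <- if (gate_x == "gaussian" && gate_y == "gaussian")
    "pearson" else "spearman"
  ht <- suppressWarnings(cor.test(x, y, method = method))
  stat_result_row(comparison_id,
                  if (method == "pearson") "pearson" else "spearman",
                  unname(ht$statistic), unname(ht$estimate),
                  ht$p.value, length(x))
}

#' Partial correlation controlling for one covariate
#'
#' First-order partial correlation
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`,
#' computed on raw values (Pearson path) or on ranks (Spearman path).
#' With `method = "auto"` the path follows the normality gate applied
#' to `x` and `y`. The p-value uses `t = r sqrt((n - 3) / (1 - r^2))`
#' with `n - 3` degrees of freedom, two-sided.
#'
#' @param x,y,z Numeric vectors (complete triples are used; n >= 5).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param comparison_id Identifier copied into the result row.
#' @param alpha Gate level for `"auto"`.
#' @return A one-row StatResult tibble (`estimate` = partial r); zero
#'   rows when degenerate (e.g. `|r_xz| = 1`).
#' @export
partial_correlation <- function(x, y, z, method = c("auto", "pearson",
                                                    "spearman"),
                                comparison_id = "x_vs_y_given_z",
                                alpha = 0.05) {
  method <- match.arg(method)
  keep <- complete.cases(x, y, z) & is.finite(x) & is.finite(y) &
    is.finite(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 5 || sd(x) == 0 || sd(y) == 0) {
    return(stat_result_row(character(0), character(0), numeric(0),
                           numeric(0), numeric(0), integer(0)))
  }
  if (method == "auto") {
    gx <- suppressWarnings(normality_gate(x, alpha))
    gy <- suppressWarnings(normality_gate(y, alpha))
    method <- if (gx == "gaussian" && gy == "gaussian")
      "pearson" else "spearman"
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  if (den <= 1e-14) {
    return(stat_result_row(character(0), character(0), numeric(0),
                           numeric(0), numeric(0), integer(0)))
  }
  pr <- (r_xy - r_xz * r_yz) / sqrt(den)
  pr <- min(max(pr, -1), 1)
  tt <- if (abs(pr) < 1) pr * sqrt((n - 3) / (1 - pr^2)) else
    sign(pr) * Inf
  p <- 2 * pt(-abs(tt), df = n - 3)
  stat_result_row(comparison_id,
                  paste0("partial_", method), tt, pr, p, n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control within one family of p-values:
#' monotone q-values and the rejection set at level `q`.
#'
#' @param p_values Numeric vector of p-values in one family.
#' @param q FDR level (default 0.05).
#' @return A list: `q_values` (monotone BH-adjusted p-values) and
#'   `reject` (logical).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(length(p_values) >= 1,
            all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  qv <- p.adjust(p_values, method = "BH")
  list(q_values = qv, reject = !is.na(qv) & qv <= q)
}
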