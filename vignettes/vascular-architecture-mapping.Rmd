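---
title: "Vascular architecture mapping with vamkit: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular architecture mapping with vamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vamkit)
library(ggplot2)
```

## The measurement model

Dynamic susceptibility contrast (DSC) MRI tracks the passage of a
gadolinium bolus through brain tissue: as the paramagnetic agent
transits the vasculature it transiently accelerates transverse
relaxation, and the signal dips. A spin-and-gradient-echo (SAGE) EPI
acquisition reads out a gradient echo (GE) and a spin echo (SE) of the
same bolus simultaneously. The two echoes see different vessels: the
spin-echo relaxation change $\Delta R_2$ is most sensitive to
microvessels below roughly 10 µm, while the gradient-echo change
$\Delta R_2^*$ responds to all calibers, including large vessels.
Pairing them voxel by voxel therefore carries information about the
local vascular architecture that neither echo carries alone.

`vamkit` implements this analysis end to end. For each voxel and echo,

$$\Delta R(t) \;=\; -\frac{1}{TE}\,\ln\!\frac{S(t)}{S_0},$$

with $S_0$ the mean of the pre-bolus baseline frames. Voxels with any
non-positive signal frame are flagged invalid rather than clipped: a
voxel either supports the full analysis or contributes nothing, which
keeps quality auditable. The gradient-echo curve is corrected for
contrast-agent extravasation with the standard two-parameter model,

$$\Delta R_{2,\mathrm{meas}}^*(t) \;\approx\; K_1\,\bar R(t)
 \;-\; K_2 \int_0^t \bar R(\tau)\,d\tau,$$

where $\bar R$ is the whole-brain (healthy hemisphere) mean curve;
$(K_1, K_2)$ are estimated per voxel by least squares and the corrected
curve is $\Delta R^*_{2,\mathrm{meas}} + K_2\int_0^t\bar R$. The
spin-echo curve is left uncorrected: the correction is defined for the
gradient-echo signal, and applying it to the spin echo is not
established practice. Both corrected curves are then fitted to a
gamma-variate bolus model

$$C(t) \;=\; A\,(t - t_0)^{\alpha}\, e^{-(t - t_0)/\beta},
 \qquad t > t_0,$$

whose time-to-peak is $t_0 + \alpha\beta$ — a continuous quantity, so
peak-time differences well below the frame spacing are measurable.

## The vascular hysteresis loop and its parameters

Plotting the two fitted curves against each other over time — $x =
\Delta R_2$ (SE), $y = \Delta R_2^*$ (GE) — traces a closed,
time-parametrized loop, the vascular hysteresis loop or vessel vortex
curve. Because the two curves peak at slightly different times, the
loop encloses area, and the traversal direction encodes which echo
leads: when the spin echo peaks first the loop runs counterclockwise.
Six parameters summarize its geometry:

* **I** (distance map): maximum separation between ascending and
  descending branch, signed by traversal direction (clockwise
  positive), in 1/s;
* **VTI** (vessel type indicator): the signed enclosed area, in 1/s²;
* **CGI** (caliber gradient indicator): slope of the loop's long axis
  ($\Delta R_2^*$ change per $\Delta R_2$ change), dimensionless;
* **BVF**: length of the long axis, a cerebral-blood-volume-fraction
  correlate, 1/s;
* **CBI** (capillary bed identifier): length of the short axis, 1/s;
* **VIPS**: the fitted SE minus GE time-to-peak, in seconds; negative
  values indicate predominance of slow-flowing venules and
  capillaries.

The sign convention is the load-bearing piece of the whole analysis,
so it is pinned by a dedicated test: a spin-echo lead must yield
orientation $-1$ and VTI, I, VIPS all negative *simultaneously*, and a
gradient-echo lead must flip all three. Healthy tissue shows the
spin-echo lead (negative I and VTI).

Three more parameters come from the fitted peaks and the corrected
curve: the vessel size index
$\mathrm{VSI} = 0.425\,(ADC/(\gamma\,\Delta\chi\,B_0))^{1/2}
(\Delta R_2^*/\Delta R_2)^{3/2}$ in µm, the microvessel density index
$Q = \Delta R_2/(\Delta R_2^*)^{2/3}$ in s^(-1/3), and relative
cerebral blood volume (rCBV), the trapezoidal integral of the
leakage-corrected $\Delta R_2^*$ curve normalized so that the
healthy-hemisphere brain mean is exactly 1.

```{r loop-example}
acq <- acquisition_params()
v <- voxel_truth(amplitude_ge = 25, amplitude_se = 3.5,
                 ttp_ge = 21, ttp_se = 20.6)
sim <- simulate_voxel(v, acq)
fit_ge <- fit_gamma_variate(
  compute_delta_r(sim$signal_ge, 1000, acq$te_ge), acq$time)
fit_se <- fit_gamma_variate(
  compute_delta_r(sim$signal_se, 800, acq$te_se), acq$time)
loop <- build_vortex_loop(fit_se, fit_ge)
loop
vhl_parameters(fit_se, fit_ge)
autoplot(loop)
```

## Parameter choices and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| TR | 1.5 | s | standard SAGE bolus sampling |
| TE (GE / SE) | 22 / 90 | ms | standard SAGE echo times at 3 T |
| frames | 10 baseline + 50 bolus | — | 15 s baseline, 75 s passage |
| $\gamma$ | 2.67513e8 | rad/(s·T) | proton gyromagnetic ratio |
| $\Delta\chi$ | 1e-7 | — (SI) | blood–tissue susceptibility difference at peak contrast concentration, from the vessel-size-imaging literature |
| $B_0$ | 3 | T | field strength |
| ADC | 0.8e-3 | mm²/s | typical healthy parenchyma; a per-voxel map may be substituted |
| peak-SNR gate | 3 | — | a fit is attempted only when the curve peak exceeds 3 baseline noise SDs |
| $r^2$ gate | 0.6 | — | fits below this are flagged invalid; >99% of clean synthetic voxels pass |
| ROUT Q | 1% | — | FDR level of outlier calls |
| BH Q | 5% | — | FDR level of the test battery |

Quality gates, constants and FDR levels are arguments of the
respective functions, so alternate choices are one keyword away; the
VSI and Q formulas are isolated in `compute_vsi()` and `compute_q()`
so alternative forms can be swapped without touching the pipeline.

Open choices the loop geometry had to settle (each behind its own
function, with the adopted default):

* branch split for I at the point of maximum distance from the origin
  (robust when the two peaks differ), and branch separation measured
  vertically at matched $\Delta R_2$ after resampling — point-to-curve
  Euclidean distance was rejected because it depends on the sampling
  density;
* CGI as the slope of the first principal component of the loop's
  point cloud (symmetric in the two axes), not a regression slope;
* axis lengths as projection ranges (max − min), matching "length of
  the axis" literally, not eigenvalue multiples;
* loops are built from the fitted curves, oversampled at 4× the
  acquisition rate (≥ 200 points), and closed at the origin; a loop
  with |shoelace area| < 1e-12 (1/s)² is degenerate: orientation 0 and
  signed parameters 0.

## The synthetic cohort generator

No patient data ship with the package; the simulator is a first-class
module that generates what the pipeline consumes. A voxel's truth is
(peak amplitude, time-to-peak, shape $\alpha$) per echo — the scale
$\beta$ follows from $ttp = t_0 + \alpha\beta$ — plus baseline
signals, optional leakage constants and a noise SD. Signals are
$S(t) = S_0 e^{-TE\,\Delta R(t)}$ with additive Gaussian noise on the
magnitude. A subject is a 24×24×6 grid (the full 120×120×24 is
supported but slow) with eight 3×3×2 VOI boxes — named for the eight
analyzed brain regions — in the hemisphere opposite a nominal lesion;
the lesion itself is a flag, not a signal model, since only healthy
hemispheres are analyzed. A cohort is 42 women and 30 men aged 20–70
(uniform), BMI drawn per sex (women 24.8 ± 4.2 flat in age; men
26.3 ± 3.2 with ~1.3 kg/m² per decade, reproducing a male-only
age–BMI correlation of ~0.5), lesions balanced left/right, and any
number of planted linear age effects on truth fields via
`cohort_effect()`.

Region baselines were set so the derived quantities land in healthy
ranges — GE peaks 17–28 1/s, SE peaks 3.6–4.8 1/s, SE leads of
0.2–0.6 s — giving Q of roughly 4–7 (in 10² ms^(-1/3)) and VSI of
9–27 µm, the right order of magnitude for adult brain. Between-subject
variability is lognormal on amplitudes (CV 8%) and Gaussian on the
SE–GE lag (SD 0.08 s); signal noise SD is 5 on a baseline of 1000.
The default planted effect used in the validation study is a
female-only +5% per decade on the GE amplitude ("caliber"), sized so
that the truth-level VSI–age correlation in women is ≈ 0.5 — strong
enough to be detected reliably at n = 42, weak enough that the male
stratum and null cohorts stay clean.

What the simulator does *not* emulate — and hence what passing tests
cannot certify about real data: Rician noise (Gaussian is adequate at
the simulated SNR and keeps the round-trip oracle exact), arterial
input function shape and dispersion, recirculation, motion, partial
volume at region borders, and within-region heterogeneity. The
generator validates the estimator chain, not the physiology.

## Statistical battery

VOI means (valid voxels only) joined to demographics give one row per
subject × VOI × parameter — 5184 rows for the full design. Each
(VOI, parameter) column is screened with the ROUT procedure (robust
IRLS location with Lorentzian weights, robust SD from the 68.27th
percentile of absolute residuals with the $n/(n-1)$ small-sample
correction, then a t-based step-up rule at Q = 1%); flagged rows are
retained with flags, never dropped silently. Sex comparisons use an
unpaired t-test when both groups pass the D'Agostino–Pearson omnibus
gate at α = 0.05, otherwise Mann–Whitney (normal approximation with
tie correction where exactness is unavailable). Age associations use
first-order partial correlations controlling BMI — on ranks when the
gate fails (the nonparametric variant is not standardized; ranks in
the same closed form is the natural choice). Sex-comparison p-values
are BH-adjusted within each parameter across the eight VOIs;
correlations are reported unadjusted by default, with
`adjust_correlations = TRUE` available since conventions differ.

The omnibus test and ROUT are implemented in the package (no installed
R package provides them); the omnibus statistic is pinned to an
independent reference implementation's values in the tests to twelve
digits.

## Validation design and what the numbers mean

`vam_validation_study()` is the package's strongest self-check and the
workload behind `scripts/acceptance.R`: 50 planted-effect cohorts and
8 null cohorts, each run end to end (simulate → relaxometry → loops →
maps → VOI means → battery). A planted replicate counts as recovered
when the female stratum's median VSI–age partial-correlation p across
the eight VOIs is below 0.05 with positive median r — the effect is
planted in every region, so the cross-region median is its natural
per-replicate summary. The male stratum's per-VOI p < 0.05 rate
estimates the false-positive rate (nominally 5%). On null cohorts
every BH rejection is false, so the mean per-family false discovery
proportion estimates the attained FDR; because BH at Q = 5% *attains*
FDR ≈ 5% under the global null, the check uses a one-sided Monte-Carlo
confidence bound (the estimate must not significantly exceed 5%)
rather than a naive `mean ≤ 0.05`, which would fail half the time by
sampling error even for a correct implementation.

Numerical facts worth knowing when interpreting fits: at TR = 1.5 s,
60 frames and peak SNR 20, the Cramér–Rao bound for the gamma-variate
time-to-peak is σ ≈ 0.19 s, and the nonlinear least-squares fit sits
essentially on that bound (empirical SD ≈ 0.18 s, bias < 0.02 s). Peak-
time *differences* of 0.4 s are nonetheless recovered to 0.01 s at
high SNR because both fits interpolate the same continuous model. The
whole-volume fitter is a vectorized Levenberg–Marquardt (all voxels
advanced simultaneously, batched 4×4 Cholesky steps, log-scale
positivity, multi-start shape initialization in the scalar reference
path); it agrees with the single-voxel `minpack.lm` route to ~1e-7 in
time-to-peak and is cross-checked against it in the tests.

Problem sizes used by the tests and the acceptance script — chosen as
a deliberate trade of grid size against replicate count, since
replicates stress the statistics harder than voxel counts do: 24×24×6
grids with 144 analyzed voxels per subject, 72 subjects per cohort,
50 + 8 cohorts in the study; 1000 repetitions for the normality-gate
calibration; 200 for ROUT.

## Known limitations

* Gaussian (not Rician) noise; adequate at simulated SNR, wrong in the
  low-SNR magnitude regime.
* rCBV is computed from the gradient-echo SAGE curve itself rather
  than a separate DSC perfusion sequence; the normalization (healthy
  hemisphere mean = 1) makes values relative, not absolute.
* The hemisphere midline is a grid-column plane; real data would use
  the image affine.
* No arterial input function deconvolution, no CBF/MTT, no motion
  correction, no spatial normalization — inputs are assumed aligned,
  masks are consumed as given.
* VOIs are homogeneous boxes; atlas-shaped regions and partial-volume
  mixing are out of scope.
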