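---
title: "Retrieving foliar delta15N from fresh-leaf reflectance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving foliar delta15N from fresh-leaf reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The nitrogen stable-isotope signature of a leaf, delta15N (the per-mil
deviation of its 15N/14N ratio from the atmospheric-N2 standard), integrates
a plant's nitrogen sources and is a workhorse tracer in ecology. Measuring
it by isotope-ratio mass spectrometry is accurate but slow and expensive,
which caps the spatial resolution of isotope mapping. `isopls` implements a
chemometric alternative: calibrate a partial least squares (PLS1) regression
of delta15N on fresh-leaf reflectance spectra (350-2500 nm, 1-nm export
grid), so that the isotope signature can be predicted optically.

The scientific subtlety is confounding. In field samples delta15N covaries
with nitrogen content and other leaf traits, so a spectral model may track
those traits rather than the isotope itself. The package therefore ships a
synthetic-data generator that reproduces the two study designs that
disentangle this: a *greenhouse labeling design*, in which delta15N is
manipulated by 15N-enriched fertilizer (0 / 10 / 20 permil nominal
enrichment) independently of nitrogen content, water content and specific
leaf area, and a *field gradient design*, in which delta15N rises from a
depleted background (about -12 permil) toward 0 permil near an N2-fixing
invader and is correlated with N content (Pearson r about 0.75). Every stage
of the chain is testable against these generators without external data.

## The inference chain

1. **Splice-jump correction** (`correct_sensor_jumps`). Field
   spectroradiometers stitch three detectors (VNIR, SWIR1, SWIR2); small
   radiometric discontinuities appear at 1000/1001 nm and 1800/1801 nm. We
   apply a per-spectrum multiplicative correction with SWIR1 as the
   reference: the VNIR segment is scaled by `r(1001)/r(1000)`, the SWIR2
   segment by `r(1800)/r(1801)`. This single-ratio convention makes the
   spectrum exactly continuous at both splices, leaves SWIR1 untouched, and
   is idempotent. (Interpolation-based variants exist; the single-ratio form
   is fully reproducible and is what our tests pin down.)
2. **Standard normal variate** (`snv_transform`). Each spectrum is centered
   and scaled to unit sample SD (divisor n-1, the chemometrics convention —
   it is what maps `[0, 1, 2]` to `[-1, 0, 1]`), removing multiplicative
   scatter differences between leaves. SNV is computed over the full
   measured axis before any range omission.
3. **Savitzky-Golay first derivative** (`savgol_first_derivative`). A
   nine-point window (four points per side), second-order local polynomial;
   the slope of the local fit, divided by the 1-nm step, estimates the
   derivative. Derivatives remove baseline offsets and sharpen overlapping
   absorption features. The four points at each edge have no centered
   window and are dropped rather than extrapolated, so no fabricated values
   enter the regression. Filter weights come from `signal::sgolay`.
4. **Range restriction** (`subset_model_range`). The noisy SWIR2 region
   (1801-2500 nm; weak lamp output) is omitted and modeling uses the
   inclusive 400-1800 nm window — 1401 candidate wavelengths on the export
   grid.
5. **PLS1 by NIPALS** (`pls1`). Predictors and response are autoscaled
   (mean-centered, weighted by 1/SD); scaling parameters are model state,
   estimated only on the fitting partition. Factors are extracted by NIPALS
   deflation; for a single response the inner iteration collapses to the
   closed form `w = X'y/||X'y||`, which is algebraically identical to
   iterated NIPALS. The object carries weights, loadings, scores, per-factor
   explained response sums of squares, and back-transformed coefficients,
   and has the usual `print`/`summary`/`coef`/`predict`/`plot`/`residuals`
   methods.
6. **10-fold cross-validation** (`cross_validate`). Random segments of size
   floor/ceiling(n/10); for each held-out segment the model — including the
   autoscaling — is re-estimated from the remainder, and held-out
   predictions are produced for every candidate factor count. The factor
   count is the **first local minimum** of RMSE_cv; if RMSE_cv decreases
   monotonically the maximum candidate is returned with a warning.
7. **Influential-outlier screening** (`detect_influential_outliers`).
   A sample is flagged when it both strongly influences the model and is
   poorly described by it. We quantify that qualitative rule as: leverage
   above `3 (A + 1) / n` (computed in the latent-score space plus
   intercept) *and* absolute studentized calibration residual above 2.5,
   with at most 5% of samples flagged per pass. All three thresholds are
   arguments; removal is logged, never silent.
8. **Martens' uncertainty test and iterated elimination**
   (`martens_uncertainty_test`, `iterative_elimination`). The k submodels
   of the cross-validation give k coefficient vectors; the jackknife
   variance of each coefficient against the full-model coefficient yields a
   t-statistic (df = k-1, two-sided alpha = 0.05). Non-significant
   wavelengths are dropped and the model re-cross-validated, iterating
   until predictive ability stops improving; equal performance with fewer
   variables is accepted (parsimony). Segments are re-randomized between
   iterations from a deterministic seed stream, so runs reproduce exactly.
9. **VIP** (`vip`). Variable importance in projection per Chong & Jun's
   formulation: a weighted sum of squared PLS weights, weighted by the
   response sum of squares each factor explains. The mean of all squared
   VIP values is exactly 1, which is why 1 (and, more liberally, 0.8) is
   the customary interpretation threshold. VIP is reported for
   interpretation only — it is not the selector.

The end-to-end drivers are `run_species_model` (per-species calibration:
filters, preprocessing, screening, elimination, report) and
`run_pooled_model` (all species pooled, stratified 2/3-1/3 train/test
split, plus a species-separation diagnostic on the factor-1 scores).
`report_run` writes the calibration-table CSV, VIP table, elimination
trace, prediction pairs, retained-wavelength list and a JSON manifest. This
package is a library, not a shell tool: these functions (with
`generate_greenhouse_dataset` / `generate_field_dataset` for simulation)
are its interface.

## Honest evaluation of the variable selection

Re-cross-validating a wavelength subset that was *chosen using all samples*
is not an honest error estimate: with about 1400 candidate wavelengths and
about 100 samples, the roughly 5% of noise wavelengths that pass the
uncertainty test by chance are exactly the ones that correlate with the
response in-sample, and a subsequent cross-validation of that subset can
report substantial apparent skill on data with no isotope effect at all
(we observe apparent cross-validated R-squared near 0.45 on such null data,
while genuinely fresh data gives R-squared near 0).

`iterative_elimination` therefore evaluates every candidate reduction by
**cross-model validation** (`nested_selection_cv`): for each held-out
segment, the entire selection — inner cross-validation, uncertainty test,
reduction, acceptance — is replayed on the remaining samples only, and the
held-out segment is predicted by the resulting fold-specific model. The
held-out samples never touch wavelength selection, factor choice or
scaling. Acceptance of a reduction, the reported RMSE_cv/R2_cv, and the
reported held-out predictions all use this estimate; the retained
wavelength set itself is still derived by the conventional full-data
procedure, so the reported variable counts and iteration numbers keep their
usual calibration-table semantics. `nested_eval = FALSE` restores the plain
(optimistic) re-cross-validation numbers for comparison. On null data the
nested estimate stays at zero skill and the elimination is rejected back to
the trivial model, which is the behavior a selection procedure must have
before its positive results can be believed.

## The synthetic-data generator

`simulate_leaf_spectrum` builds reflectance as a smooth species baseline
(low visible reflectance, red-edge sigmoid, NIR plateau with a gentle SWIR
decline) multiplied by Gaussian absorption features, then distorted by
per-sensor splice factors and heteroscedastic noise (SWIR2 noise roughly
6x the VNIR level, emulating a weak halogen source in that region). It is a
stylized, controllable generating model — deliberately *not* a
radiative-transfer leaf model: controllability, not realism, is the goal.

Feature centers follow the leaf-biochemistry literature: chlorophyll bands
at 430, 460, 640, 660, 678 nm; protein/N-bond features at 910, 1020, 1165,
1270, 1375, 1510, 1690, 1730, 1770 nm; water bands at 970, 1200, 1450,
1780, 1940 nm. Three trait sensitivities act on the features: nitrogen
content adds depth to chlorophyll/N-bond features, gravimetric water
content adds depth to water bands, and **delta15N acts fractionally on the
width** of the chlorophyll and N-bond features (0.008 fractional width
change per permil by default) — band-width modulation is the mechanism
hypothesized for isotope effects on chlorophyll absorption; a depth-mode
switch is provided. Species express the isotope response with different
weights across the band families (chlorophyll, NIR protein and SWIR
protein bands): one species mainly in the SWIR protein bands, one mainly
in the chlorophyll bands, one with opposite sign — a stylized counterpart
of species using freshly assimilated nitrogen differently. Within a species the response is consistent, so
species-specific calibrations work; across species the responses conflict,
which is what makes the pooled model fail within species while its leading
factors separate the species — the qualitative pooled-model outcome the
package's diagnostics check.

The greenhouse design: 16 / 12 / 11 plants for the three species, randomly
allocated to 0 / 10 / 20 permil treatments (the smallest species to 0 / 20
only), nine leaves per plant (three young, three mature, three
drought-stressed). Foliar delta15N is the species baseline plus the
treatment enrichment scaled by a leaf-type uptake fraction (mature leaves
take up less; uptake fails entirely in mature leaves of the sclerophyllous
species — those 33 samples are what `exclude_unlabeled_mature` removes,
leaving 66) plus 1 permil leaf-level noise, giving within-species ranges of
roughly 16-19 permil. N%, GWC and SLA are drawn independently of treatment,
so the within-species rank correlations of delta15N with the other traits
sit near zero (`check_covariate_independence` is the gate). The field
design mixes a -12 permil background with 0 permil fixed nitrogen, the
fixed fraction decaying exponentially with distance (e-folding 10 m, 0.79
at the canopy edge, so the gradient spans about -12 to -2.5 permil), with
N content tracking the same mixing fraction plus independent noise,
calibrated to a Pearson correlation near 0.75 inside the 0.47-0.96% band.

Default effect sizes and noise levels were calibrated once so that the
package's property suite sits comfortably inside its bands — per-species
cross-validated R-squared around 0.7 (the regime reported for real
fresh-leaf calibrations is 0.53-0.73), RMSE_cv near 15% of the response
range, zero skill when the isotope sensitivity is switched off — and then
frozen as the defaults.

Isotope bookkeeping for labeling recipes is exact
(`delta_after_label_addition`): delta values convert to atom fractions via
the AIR ratio 0.0036765, moles of 15N and total N are summed over pool and
additions, and converted back. With a 14.8 mmol N pool (an assumption
consistent with a modified Hoagland solution; the package states it rather
than hiding it) the canonical per-10-permil recipe — 0.274 umol KNO3 at 98
atom-% plus 0.145 umol (NH4)2SO4 at 95 atom-% (two N per molecule) —
shifts the pool by +10.03 permil.

## Numerical choices and degenerate inputs

* SD divisors are n-1 throughout (SNV, autoscaling), for consistency.
* NIPALS truncates trailing factors whose score sum-of-squares falls below
  1e-12 of the initial X sum-of-squares (rank exhausted), with a warning.
* Zero-variance predictors are dropped with a warning and report zero
  coefficients; constant spectra make SNV error; zero reflectance at a
  splice reference band makes the jump correction error; splice factors
  outside [0.5, 2] warn (suspect spectrum).
* Reflectance above 1 (specular glare) is admitted with a warning, never
  clipped — clipping would bias SNV.
* In the uncertainty test, a coefficient with zero jackknife variance is
  significant iff it is nonzero.
* First-minimum factor selection returns A_max with a warning on monotone
  RMSE_cv sequences; ties are broken toward fewer factors by the strict
  `rmse(A) < rmse(A+1)` comparison.
* Elimination acceptance uses a 1e-3 relative tolerance (parsimony: equal
  error with fewer variables is accepted) and a hard cap of 10 passes.
* All randomness flows from explicit seeds; every stochastic function
  restores the caller's RNG state.

## Problem sizes used by the test suite

The property suite runs the full chain on generator output at the design's
native size (about 100-144 leaves per species, 1401 candidate wavelengths),
with 10-seed medians for the parameter-recovery and negative-control
properties and 50 replicates for the false-positive-rate check; the
algebraic oracle checks (least-squares equivalence, independent-PLS
agreement) use 20 random 30 x 12 instances. These sizes were chosen so the
whole suite completes in a few minutes while keeping the medians stable.

## What passing tests do and do not show

The generator's spectra are smooth Gaussian-feature composites with
Gaussian noise; real leaf spectra have specular and structural effects
(trichomes, cuticle gloss), instrument drift, and absorption features that
are neither Gaussian nor independent. A pipeline that recovers planted
signals here is necessary-but-not-sufficient evidence for real data; what
the suite *does* establish is the internal correctness of every stage (the
algebra against independent oracles), the honesty of the error estimates
(negative controls, mutation tests), and the qualitative behavior of the
design (independence in the greenhouse, covariation in the field,
pooled-model failure across heterogeneous species).

## Known limitations

* PLS2, sparse PLS and kernel PLS are out of scope; so are alternative
  selectors (CARS, genetic algorithms, interval PLS) — VIP is reported for
  interpretation, never used as the selector.
* The jump correction implements the single-ratio convention only.
* The generator does not model canopy geometry, kriging surfaces or
  instrument line-shape differences; resampling from native 1.4 / 2-nm
  sampling to the 1-nm grid is assumed done by the instrument export.
* The outlier rule is a stated quantification of a qualitative practice;
  its thresholds are defaults to be examined, not dogma.
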