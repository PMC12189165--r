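---
title: "Modelling the development of lateral-angle sexual dimorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the development of lateral-angle sexual dimorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrousgrowth)
```

## The scientific question

The lateral angle of the internal acoustic meatus — the acute angle
between the canal's lateral wall and the posterior surface of the petrous
bone — is used in osteology as a sex marker, classically with the rule
that an angle above 45° indicates a female and 45° or below a male.
Reported accuracies vary wildly between populations and measurement
methods (see `lateral_angle_literature()`), and it has been unclear
whether the dimorphism exists before adulthood at all.

`petrousgrowth` implements a complete analysis pipeline for this
question on cohorts of known-sex, known-age specimens: does the angle
differ between boys and girls during childhood, how strongly is it
coupled to overall cranial breadth, and in which age window does
male and female cranial-breadth growth diverge? The package's central
bespoke component is the last of these: a bootstrap procedure that puts
pointwise bias-corrected and accelerated (BCa) confidence bands around
the female-minus-male difference of LOESS growth curves and reports the
contiguous age windows in which the band excludes zero.

## The data model

A cohort is a flat table of specimens: identifier, collection, sex
(`F`/`M`), age at death in decimal years, lateral angle in degrees
(possibly missing), and biauricular breadth (AUB, Martin's definition)
in millimetres (possibly missing). Validation is strict: ages are
non-negative, angles must lie strictly inside (0°, 90°), breadths
strictly inside (40, 180) mm, and missing values are empty cells — a
sentinel such as −1 is rejected rather than silently absorbed. Unknown
collections are mapped to `"other"` with a warning so the pipeline
generalizes beyond the four named collections. Infant ages such as 0.1
years are taken as-is; no month/day parsing is attempted.

Exclusion rules mirror the study design this package emulates: a global
inclusion window of birth to 30 years, a collection-specific cap (Graz
specimens above 21 years are excluded because the older subjects formed
a deviating cluster of unknown provenance), and removal of rows flagged
for cranial trauma or pathology. `apply_exclusions()` logs the first
rule each removed row violated and is idempotent.

Descriptive summaries (`summarize_cohort()`) report n, mean, sd, median,
min and max per (collection, sex, variable) over non-missing values. A
single-observation stratum reports `NA` for the standard deviation: the
n−1 denominator is undefined, and reporting 0 would fabricate precision.

## The synthetic cohort generator

No raw specimen table ships with the package, so a generator emulates
the statistical structure the analysis assumes. It is first-class,
tested code, and its defaults *are* the study conditions; they are not
tuning knobs.

Biauricular breadth follows a logarithmic growth curve shared by the
sexes plus a male-only pubertal ramp:

\[
\mathrm{AUB} = b_0 + b_1 \log(1+\mathrm{age}) +
\delta\,r(\mathrm{age})\,[\mathrm{male}] + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma_\mathrm{aub}^2),
\]

where \(r\) is a logistic ramp with midpoint \(\tau\) and scale \(w\),
shifted and rescaled so that \(r(0)=0\) exactly (both sexes share the
birth mean \(b_0\); no pre-pubertal dimorphism) and \(r \to 1\) in
adulthood. The lateral angle is coupled linearly to breadth:

\[
\mathrm{LA} = a_0 + a_1\,\mathrm{AUB} + c\,[\mathrm{male}] + \eta,
\qquad \eta \sim N(0, \sigma_\mathrm{angle}^2) .
\]

Defaults: \(b_0 = 75\) mm, \(b_1 = 14\) mm per log-year,
\(\delta = 5.6\) mm, \(\tau = 13\) y, \(w = 1.5\) y,
\(\sigma_\mathrm{aub} = 5\) mm, \(a_0 = 75\)°, \(a_1 = -0.274\)° per mm,
\(\sigma_\mathrm{angle} = 5\)°, \(c = 0\). The slope \(a_1\) is anchored
to the published covariate-adjusted partial coefficient of breadth; the
growth parameters are calibrated so the block means track the published
collection summaries (`reference_collection_summary()`) — in particular
the adult male−female breadth gap of 5.6 mm (124.5 − 118.9) — and the
log + logistic-ramp form is the simplest curve matching the described
growth pattern (fast early growth, divergence starting around age ten,
clear separation by sixteen). This calibration is documented, not
asserted as biological ground truth.

Whether the angle's dimorphism is purely breadth-mediated or has a
direct anatomical sex component is exactly the open biological question;
the generator exposes `sex_effect_direct` (\(c\), default 0) so both
hypotheses can be simulated.

Four age blocks mimic the four-collection design, with weights
50:41:17:96 and uniform ages within 0.1–11, 3–21, 0.1–3 and 12–30 years
respectively; the modern block contributes breadth only, and the angle
is generated only at or below a configurable age cap (21 y). The
default `n_per_sex = 100` reproduces the study scale (about 200
specimens, roughly half of them with angle measurements). Each cohort
uses one private, explicitly seeded random stream; the caller's RNG
state is untouched, and a given seed reproduces a cohort byte for byte.

What the generator does *not* emulate: population heterogeneity between
collections (all blocks share one growth curve), non-Gaussian residuals,
age-dependent variance (real newborns are more variable), measurement
method effects, and any coupling with cranial length. Passing tests
therefore demonstrate the correctness and calibration of the procedure
under the assumed structure, not the biological conclusions on real
material.

## The regression suite

`model_suite()` fits three least-squares models: (a) angle on age, (b)
the simple angle–breadth regression, and (c) angle on age and breadth
jointly — the covariate-adjusted model that asks whether age retains
predictive value once cranial breadth is accounted for. Fitting is
delegated to `stats::lm` on complete cases (no imputation); inference
uses two-sided t-tests with n − p − 1 degrees of freedom, and the
suite's four primary slope p-values are Holm-adjusted
(`holm_adjust()`, a front end to `stats::p.adjust`).

Two reporting choices deserve a note. First, coefficients are raw
slopes in natural units (degrees per year, degrees per mm), because the
published partial coefficient of breadth (−0.274) is on that scale;
standardized betas are available behind `standardize = TRUE` since
"β" labels in the literature are ambiguous. Second, the direction of
the simple angle–breadth regression is reported both ways with the
direction-invariant R², because published slope values for the simple
models are not unambiguously attributable to one direction; only the
shared R² and the clearly specified multiple-regression coefficients are
treated as anchors. Model (c) uses untransformed age; the
log-transformed age axis appears only as a display convention for
breadth-growth plots.

## Classification

`roc_curve()` sweeps thresholds over the unique score values (ties
grouped into one step) with the orientation "higher score → positive",
the positive class defaulting to female since females have the larger
angles on average. The AUC is the Mann–Whitney probability with half
credit for ties, identical to the trapezoidal area under the stored
curve; an AUC below 0.5 is reported as-is rather than flipped, so a
score that runs against its expected orientation is visible. The
chance-level AUCs this produces on subadult cohorts — near 0.49 for the
angle — are the package's reproduction of the finding that the angle
carries no sex signal before puberty.

`fit_logistic()` is a deterministic IRLS logit fit (`stats::glm`,
tolerance 1e-8, at most 100 iterations) with perfect separation raised
as an explicit error and near-separation surfaced as a warning. No
pseudo-R² is reported: which pseudo-R² underlies published logistic
summaries for comparable data is unstated, so asserting one would be
guesswork.

`classify_cutoff()` applies the classic fixed-cut-off rule exactly:
score strictly above the cut-off → female, at or below → male. A
specimen at exactly 45° classifies male under the default. The Youden
index is available as a convenience (`youden_threshold()`); no further
optimal-cut-off machinery is provided, since the package's own analyses
argue against universal cut-offs.

## The divergence procedure

The bespoke core asks: *over which ages does male cranial-breadth
growth outpace female growth?*

1. **Smoothers.** One LOESS fit per sex of breadth on age:
   at each evaluation point, weighted least squares of degree 1 over
   the ⌈span · n⌉ nearest training points, tricube weights on distance
   scaled by the neighbourhood radius, no robustness iterations. The
   implementation is written from this definition (closed-form local
   solves, vectorized over the evaluation grid) and is verified in the
   tests against per-point weighted fits and against
   `stats::loess(surface = "direct")` to 1e-8. Predictions outside the
   training range are refused.
2. **Difference curve.** Both smoothers are evaluated on a common age
   grid — 0.5-year steps over the *overlap* of the sexes' observed age
   ranges, so neither curve extrapolates — and the female-minus-male
   difference is taken. Negative values mean males are larger.
3. **Bootstrap.** `B = 1000` resamples with replacement, stratified by
   sex with each sex's n preserved (the resampling scheme is recorded in
   the report; pooled resampling is available as an option). The full
   difference curve is recomputed per replicate. Replicates in which a
   local fit is rank-deficient are dropped and counted; more than 10%
   failures aborts with advice to increase the span.
4. **BCa band.** Per grid age, a bias-corrected and accelerated
   interval over the replicate values: the bias term
   \(z_0 = \Phi^{-1}(p)\) with \(p\) the proportion of replicates below
   the observed value (ties half-counted, clamped to
   \([1/(B+1),\,B/(B+1)]\) with a warning when it hits 0 or 1); the
   acceleration \(a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})\) from
   leave-one-*case*-out jackknife curves (stratified recomputation,
   \(d_i\) = jackknife mean minus the i-th leave-one-out value); and
   type-7 empirical quantiles of the replicates at the BCa-adjusted
   levels. With \(z_0 = a = 0\) this reduces exactly to the percentile
   interval, which the tests assert. Identical replicates at a grid age
   yield the degenerate point interval with a warning.
5. **Windows.** Grid ages whose interval excludes zero are flagged;
   consecutive flagged ages are merged; runs shorter than `min_run = 2`
   grid points (one year at the default grid) are discarded as flicker.
   Each window reports its sign (which sex is larger).

The band is *pointwise*, as in the procedure it reproduces: no
simultaneous (family-wise) adjustment across grid ages is applied, and
window onsets should be read accordingly.

### Numerical and design choices

* **Span.** No span is stated for the original smoothing, so the
  conventional default 0.75 with local degree 1 is used; both are
  configurable. Degree 1 is stabler than degree 2 at the edges of the
  age range, where adolescent data are sparse.
* **Wide-span bias.** A span of 0.75 averages over most of the age
  axis, which smears sharp features: a pubertal ramp of width ~1.5
  years appears in the smoothed difference curve as a gradual slope
  beginning several years earlier. With large samples the pointwise
  band is tight enough that this smoothing bias itself becomes
  "significant", so the *onset* of the flagged window sits earlier
  than the underlying ramp midpoint. The acceptance simulations
  measure exactly this behaviour; narrower spans localize onsets
  better at the cost of rougher curves. This is an inherent property
  of smoothing-based divergence detection worth keeping in mind when
  interpreting window boundaries.
* **Resampling unit.** Whether the original bootstrap resampled within
  sex or pooled is not stated; stratified-by-sex is the default (it
  preserves the two design sizes) and the choice is recorded in the
  report metadata, with pooled available via `stratified = FALSE`.
* **Band type.** The description of the original procedure mixes
  "prediction intervals" and "confidence intervals"; this package
  implements 95% BCa *confidence* bands on the difference curve, per
  the explicit bias-corrected-and-accelerated phrasing.
* **Age axis.** Smoothing is on raw age by default (log-age is not
  stated for the original fits); the regression display of breadth
  against log-age is a plotting convention only.
* **Quantile convention.** Type-7 quantiles, held fixed so the
  percentile-reduction identity is exact.

## Problem sizes and test design

The test suite builds all fixtures in code. Oracle tests use exact
closed forms (normal equations, exhaustive pairwise AUC, hand-computed
Holm sequences, single-point tricube fits) on small inputs. The
simulation-based acceptance checks use cohorts of 300 per sex with
B = 500 bootstrap replicates over 50 seeds for parameter recovery and
null calibration of the divergence procedure, and 200 seeds of
study-sized cohorts for the null AUC calibration; these sizes give
binomial standard errors of a few percent on the estimated rates while
keeping the full suite in the minutes range on one CPU. The acceptance
script analyses one study-sized cohort (100 per sex, B = 1000) per
seed.

## Limitations

* The pipeline analyses the cohort as a single population; collection
  effects are handled only by exclusion rules, not by hierarchical
  modelling (deliberately out of scope).
* Divergence bands are pointwise; families of grid ages are not
  jointly controlled, and window onsets inherit the smoothing bias
  discussed above.
* The synthetic generator's simplifications mean calibration results
  transfer to real material only to the extent the assumed structure
  holds; with real data the same functions run unchanged on an input
  table.
* Angle measurement itself (from CT scans or casts) is out of scope;
  the package starts from measured values.
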