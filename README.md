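# petrousgrowth

Tools for studying how sexual dimorphism of the **lateral angle** of the
petrous bone — the acute angle between the lateral wall of the internal
acoustic meatus and the posterior surface of the petrous pyramid — emerges
during childhood, and how strongly the angle is coupled to cranial breadth.

The lateral angle is a classic osteological sex marker (angle > 45° →
female, ≤ 45° → male), frequently applied to fragmentary and cremated
remains because the petrous bone survives so well. Its reported accuracy,
however, ranges from coin-toss to over 80% across populations. This package
implements, as tested reusable R functions, the analysis needed to probe
why: cohort ingestion with exclusion rules and descriptive summaries,
regression models linking lateral angle (LA), age and biauricular breadth
(AUB), ROC/AUC and fixed-cut-off sex classification, and a bootstrap
procedure that localizes the age window in which male and female
cranial-breadth growth diverge. A synthetic four-collection cohort
generator emulates the data structure of historical subadult skull
collections plus a modern CT reference sample, so every stage is testable
without restricted specimen data.

## The statistical core

* **Model suite** (`model_suite`): least-squares fits of LA ~ age,
  LA ↔ AUB (both directions, direction-invariant R²), and the
  covariate-adjusted LA ~ age + AUB, with Holm-corrected slope p-values.
* **Classification** (`roc_curve`, `fit_logistic`, `classify_cutoff`):
  ROC threshold sweep whose AUC equals the Mann–Whitney probability
  P(score_F > score_M) with half credit for ties; logistic IRLS fit with
  explicit separation handling; the 45° rule applied exactly.
* **Growth divergence** (`bootstrap_difference`,
  `detect_divergence_windows`): sex-stratified LOESS curves of AUB on age
  (tricube weights, local degree 1, span 0.75 by default), the
  female−male difference on a shared age grid, B = 1000 stratified
  bootstrap replicates, and per-grid-age BCa intervals

      z0 = Φ⁻¹(#{diff* < diff}/B),   a = Σd³ / (6 (Σd²)^{3/2}),

  with jackknife-based acceleration; contiguous grid ages whose 95% band
  excludes zero form the reported divergence windows.
* **Synthetic cohorts** (`simulate_cohort`): AUB = b₀ + b₁·log(1+age) +
  δ·ramp(age)·[male] + noise with a logistic pubertal ramp (midpoint
  τ = 13 y), and LA = a₀ + a₁·AUB + noise with a₁ = −0.274° per mm, so the
  angle's dimorphism is breadth-mediated by default.

## Worked example

```r
library(petrousgrowth)

tab <- simulate_cohort(sim_config(n_per_sex = 100, seed = 42))

ms <- model_suite(tab)
print(ms$model_c)
#> Least-squares fit: lateral_angle_deg ~ age_years + aub_mm
#>         term estimate      se       t         p
#>  (Intercept) 68.12140 6.85504  9.9374 1.019e-16
#>    age_years -0.03088 0.16379 -0.1886 8.508e-01
#>       aub_mm -0.20823 0.07735 -2.6921 8.289e-03
#> R2 = 0.2263, adjusted R2 = 0.2113, residual sd = 5.042, n = 106

roc_curve(tab, "lateral_angle_deg")
#> ROC for lateral_angle_deg (positive = F, higher-score->positive):
#> AUC = 0.4913  [53 positive / 53 negative]

ens <- bootstrap_difference(tab, B = 1000, seed = 42)
detect_divergence_windows(ens)
#> Divergence windows (runs of >= 2 grid ages whose BCa interval excludes 0):
#>  start_age  end_age sign
#>   12.41348 28.91348  M>F

classify_cutoff(tab)
#> Cut-off classification (lateral_angle_deg > 45 -> F): accuracy 0.5283
#> on 106 specimens (F: 0.6604, M: 0.3962)
```

Read: once cranial breadth is in the model, age carries no information
about the lateral angle (p = 0.85) while breadth remains a significant
negative predictor; the angle classifies subadult sex no better than
chance (AUC ≈ 0.49, 45°-rule accuracy ≈ 0.53); and male breadth growth
pulls away from female growth from early puberty onward (window flagged
from ~12 years, males larger). `run_full_analysis()` executes all stages
in one call and `write_report()` serializes the result (JSON + text +
difference-curve CSV).

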