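---
title: "Phenotypic frailty scoring: model, conventions and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic frailty scoring: model, conventions and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofrail)
```

## The model

The phenotypic (Fried-type) frailty score counts deficits across five
domains: weight loss, exhaustion, weak grip, slow walking and low physical
activity.  In populations without applicable external normative values,
the performance cutoffs are derived *within* the study cohort: weak grip
and slow walk are the lowest sex-specific quintile of covariate-adjusted
performance, low activity the highest sex-specific quintile of sitting
hours.  This construction has a consequence worth keeping in mind when
reading prevalence tables: among participants with a measure observed, the
corresponding component flags almost exactly 20% per sex *by
construction*, whatever the population's absolute performance level.

### Measurement aggregation

Raw field measurements arrive as repeated trials.  `summarize_performance()`
applies the standard aggregation rules: maximum of up to four grip trials
(two per hand, Jamar-style dynamometry); 4 m divided by the fastest of two
timed walks from a standing start (the course length is an argument for
protocols using other distances); chair-stand time passed through; blood
pressure as the mean of the second and third of three seated readings
(discarding the first, which is systematically elevated).  Aggregation is
permutation-invariant and monotone — adding a worse trial never changes
the summary — and a measurement with no usable trial is missing, never
imputed.

### Covariate adjustment

Grip depends on body size and walk speed on leg length, so raw values are
adjusted linearly before quantile derivation, within sex:

    adjusted = raw − (covariate − reference) · slope

with BMI (kg/m²) as the grip covariate and height (cm) as the walk
covariate.  In *derive* mode `fit_adjustment()` estimates the slope by
ordinary least squares in the sex stratum (at least 10 complete pairs, a
degenerate constant covariate is an error) and takes the stratum mean
covariate, rounded to one decimal, as the reference.  In *fixed* mode a
published equation set is applied verbatim; `reference_adjustments()` and
`reference_cutoffs()` carry one such set, derived in a West African
population cohort of adults aged 40+ (slopes 1.17 / 0.44 kg per BMI unit
and 0.00579 / 0.00849 m/s per cm for men / women; cutoffs <37.1 / <25.0 kg,
<0.821 / <0.720 m/s, ≥34 / ≥36 sitting hours).  Running derive mode on the
cohort that produced a cutoff set reproduces fixed-mode flags exactly; the
tests assert this identity.

### Scoring and categories

One point per positive domain.  0 = non-frail, 1–2 = prefrail, ≥3 = frail.
A participant with any missing domain is `unable_to_score` — the literal
rule — even with three observed positives.  Because previous work finds
that people unable to complete testing have prognosis at least as poor as
the frail, the unable group is kept as an explicit category and the
association battery supports both codings: `frail_only` (unable excluded)
and `frail_or_unable` (merged).  The alternative reading, in which ≥3
observed positives already label a participant frail despite a missing
domain, is available behind `strict_missing = FALSE` and is off by
default.

## Numerical conventions

These are the decisions on which printed numbers silently depend; each is
a package decision, documented here and configurable where reasonable.

* **Quantile definition.** Linear interpolation between order statistics
  (`stats::quantile` type 7, the R default).  Published cutoffs depend on
  the rule at the third decimal, and the convention is rarely stated in
  papers; `quantile_type` is an argument to every deriving function.
* **Strictness at thresholds.** Follows the printed symbols exactly:
  grip/walk flag strictly below the cutoff (`<`), sitting flags at or
  above (`>=`), weight loss strictly above 4 kg (integers: ≥5),
  exhaustion at or above the "3–4 days a week" item level, hypertension
  strictly above 140/90 mmHg, diabetes strictly above 200 mg/dL random,
  126 mg/dL fasting, 6.5% HbA1c, and the comparison (sarcopenia guideline)
  block strictly below 27/16 kg and 0.8/0.6 m/s and strictly above 15 s.
  The asymmetry between `<` for performance quintiles and `>=` for
  sitting is deliberate, not an accident.  A consequence of strict `<`
  with heavy ties: if every adjusted value in a stratum is identical, the
  cutoff equals that value and no one is flagged (whereas all are flagged
  for sitting).
* **Rounding.** Report percentages are rounded half *up* to one decimal
  (`round_half_up()`, `format_percent()`); base R's `round()` is
  half-to-even and reproduces published tables incorrectly in about one
  cell in twenty.
* **Serialization.** Cutoff sets are written as JSON with 17 significant
  digits so that fixed-mode reuse is bit-identical to the deriving run,
  including at tie boundaries.
* **Missing data.** An empty CSV cell is `NA` in memory; zero is never
  treated as missing (a 0 kg grip is a validation error, not an absence).
  Missingness propagates: every derived quantity with a missing input is
  missing, and nothing downstream imputes.  Cutoff derivation uses all
  participants with that measure present, so per-component denominators
  differ — the component tables carry numerator, denominator and missing
  count for exactly this reason.

## Clinical classifiers

Hypertension: self-reported prior diagnosis or treatment, or mean systolic
> 140 mmHg, or mean diastolic > 90 mmHg.  One elevated mean suffices even
if the other is missing; with no self-report and no usable blood pressure
the status is missing, and a normal systolic with missing diastolic cannot
rule the condition out, so it is missing too.  Diabetes follows the same
pattern over self-report, random glucose, fasting glucose and HbA1c, and
is negative only when at least one input is observed and none is positive.
Both classifiers carry a provenance tag (`self_report` / `measured` /
`both`).

ADL impairment is moderate-or-worse difficulty for transfers, toileting,
dressing, bathing and eating, and some-difficulty-or-worse for walking
(whose questionnaire offers no mild/moderate/severe split).  Items are
stored on one ordinal 0–4 scale so each rule is a single comparison.
"Unable to do" counts as impaired.  "Do not want to do" is treated as
missing for that item: the response option carries no severity
information, and assigning it either way would be an invention — this is a
package decision on a point the source conventions leave unassigned, and
it is deliberately conservative.

## The wealth index

Socioeconomic position is summarised from ordinal asset items (water
source, toilet type, rooms, cooking fuel, livestock, land, electricity,
furniture, watch, cart, phone, bank account) as the first principal
component of their *polychoric* correlation matrix — ordinary Pearson PCA
on ordinal codes underestimates associations between coarse items.

The polychoric estimator is the standard two-step maximum-likelihood
procedure: thresholds fixed at inverse-normal transforms of the marginal
proportions, then one-dimensional likelihood maximisation over the latent
correlation, bounded in [−0.999, 0.999] for stability.  Two-step rather
than full ML because it is fast, standard, and adequate at survey sample
sizes; the test suite pins the estimate against a brute-force likelihood
grid search whose cell probabilities are computed by an independent
quadrature route.  Bivariate normal rectangle probabilities use the
single-integral arcsine identity with adaptive quadrature (accurate to
~1e-10).  Empty ordinal categories are collapsed with a warning.  A
correlation matrix that fails positive semi-definiteness (possible, since
entries are estimated pairwise) is repaired by eigenvalue clipping at
1e-6 with the unit diagonal restored, and the repair is flagged on the
result object.

Participants are scored by mapping each response to its category mean
normal score and projecting on the first eigenvector; a missing item
contributes the item mean (zero), a deliberate mean-imputation *only at
the scoring step* so that a single missing asset does not delete a
participant from the wealth distribution.  The eigenvector sign is
arbitrary, so it is anchored on the electricity item (presence =
wealthier); quintile 1 is the poorest fifth, using the same quantile rule
as the frailty cutoffs.  The test surface for the index is latent
recovery — rank correlation with a known generating factor above 0.8 at
n = 2000 — rather than coefficient equality with any particular published
index, whose exact item codings are not reproducible from the outside.

## The association battery

* **Contingency tests.** Pearson chi-squared without continuity
  correction, switching to Fisher's exact test whenever *any* observed
  cell is five or less.  The switch is a pure function of the observed
  table; the boundary (cell = 5 vs 6) is unit-tested, and the Fisher
  p-value is pinned to exhaustive hypergeometric enumeration.
* **Trend.** Mantel–Haenszel linear-by-linear 1-df chi-square across the
  ordered categories non-frail / prefrail / frail with equally spaced
  integer scores and the (N−1) variance form: the statistic is
  (N−1)·r², r the Pearson correlation between group score and binary
  outcome over the N subjects.  Unable-to-score is excluded from trend
  tests.  In the two-group case the statistic is exactly (N−1)/N times
  the Pearson chi-square, an identity the tests verify.
* **Odds ratios.** Crude: cross-product with Woolf log-scale 95% CI and
  the Haldane–Anscombe +0.5 correction when a cell is zero.  Adjusted:
  maximum-likelihood logistic regression (`stats::glm`), exposure
  references declared explicitly (married/cohabiting, wealth quintile 1,
  disease absent), Wald rather than profile intervals to match the
  reporting conventions of epidemiological tables.  Separation — a level
  with no outcome variation, a divergent coefficient or an exploding
  standard error — is reported as non-estimable rather than as a huge
  number.  An unadjusted logistic model on a single binary exposure
  reproduces the crude cross-product exactly (saturated-model identity,
  tested).
* **Group contrasts.** Student's t for variables treated as normal,
  Mann–Whitney U otherwise (exact for small untied samples, pinned to
  rank-split enumeration).
* **Conventions.** Two-sided α = 0.05 throughout; no multiple-testing
  correction, matching the descriptive-epidemiology reporting style this
  battery reproduces.  Age enters adjusted models linearly in years —
  for the multivariable model that is the stated convention ("per year"),
  for the age/sex-adjusted models it is a package decision taken for
  consistency.

## The synthetic cohort generator

Field data of this kind are typically under restricted access, so the
package ships a generator whose defaults *are* the study conditions the
pipeline is tested under, calibrated to the published moments of a rural
West African cohort (n = 2973, 50.6% female, age bands
41.6/28.8/18.4/9.0/2.3% from 40–49 to 80+): sex-specific grip 44.9 (10.4)
/ 31.1 (7.3) kg, walk 1.04 (0.27) / 0.89 (0.23) m/s, BMI 21.7 (3.5) /
22.4 (4.8) kg/m², chair-stand medians 13 / 15 s, sitting 25.6 (14.1)
h/week, disease prevalences (hypertension 36.7%, diabetes 6.4%, ...), and
per-measurement missingness taken from the published per-component
missing counts (grip 38/2973, walk 43, chair 160, weight change 103,
exhaustion 1, sitting 11).

### Mechanism

Each participant receives latent grip and walk values:
sex- and age-specific mean, plus the covariate link (the published
adjustment slopes, so derive-mode fits recover realistic slopes), minus a
scaled *frailty liability* — a centred weighted sum of the participant's
disease indicators — plus residual noise.  Observed trials are the latent
value plus small trial noise (1 kg, 0.2 s), offset by the expected
maximum of the corresponding number of standard normal draws so that the
*aggregated* measure (max of four, fastest of two) is unbiased for the
latent value; this both exercises the aggregation rules and keeps the
configured means interpretable as measure means.  Ages are drawn
uniformly within their band (integer years); band membership is all the
published composition provides.

Per-decade decline slopes (grip −5.5/−3.0 kg, walk −0.10/−0.09 m/s for
men/women, sitting +3 h) were back-calculated from the published
per-age-band low-performance prevalences under the normal model: the
within-age SD is the marginal SD with the age and covariate variance
components removed, and the slope is chosen so the band-specific
probability of falling below the cohort quintile reproduces the published
gradient (8% → 88% for male grip across the age range, and so on).  The
residual-SD decomposition is validated up front: a slope too steep for
the marginal SD is a configuration error, not a silent truncation.

Self-reported domains (exhaustion, weight loss) follow logistic models on
age, sex and liability, with intercepts calibrated by simulation at
n = 30000 to the published component prevalences (20.7%, 8.9%).  The two
exhaustion items are generated so that the "either item" rule is
non-trivially exercised.  ADL items follow logistic models on standardized
performance deficit and liability plus a shared person-level disability
factor (coefficient 2.6); the shared factor is what makes impairments
co-occur, so that any-ADL prevalence (28.6%) sits only a little above the
walking-item prevalence (24.8%), as observed.  Sitting hours use a
truncated-at-zero normal with an analytic one-step mean correction so
truncation does not inflate the configured mean.  Truncation everywhere is
by resampling, not clipping, avoiding point masses at the bound.

Blood pressure and glycaemia are generated conditionally on true disease
status with self-report recorded for a fraction of the truly diseased, so
the rule-based classifiers recover approximately the configured
prevalences from a mixture of self-report and measurement — the same
two-source structure the classifiers are designed for.  Asset items are
thresholded loadings on a single latent wealth factor mildly negatively
associated with age and liability.

The hypertension liability coefficient (0.52) is the one deliberately
*effect-targeted* default: it was calibrated by simulation so that the
full pipeline's age/sex-adjusted frail-only odds ratio for classified
hypertension has geometric mean ≈ 1.8 across replicates at n = 3000 —
the magnitude of the published hypertension association — giving the
parameter-recovery test a known generating truth.  All calibrated values
were frozen before the acceptance suite was written.

### What the generator does not emulate

Passing tests on this generator demonstrate correctness of the *pipeline*
under realistic moments, gradients and missingness — not distributional
fidelity to any real cohort.  Known departures:

* Latents are (truncated) normal or log-normal.  Real performance
  distributions are skewed; with the published mean and SD, a normal walk
  distribution puts ~18% of men below the fixed 0.8 m/s comparison
  threshold where the real cohort observed 9.3%.  Quintile-*derived*
  components are immune (20% by construction), but fixed-threshold tail
  rates from the generator should not be read as population estimates.
* Diseases are independent of age and of each other, so adjusted and
  crude odds ratios nearly coincide by design; confounding structure is
  deliberately simple so the recovery test has a clean truth.
* Missingness is completely at random, whereas real inability to complete
  testing is strongly health-related.
* No household structure, survey weights, or non-response mechanism
  (the source study reported 76% response; non-response is noted, not
  modelled).

## Problem sizes in the test suite

Chosen as the package's own balance of resolution against runtime: the
main quintile-conservation and recovery checks use n = 3000 (the scale of
the motivating cohort); effect recovery uses 100 replicates (coverage
resolution ±3 percentage points); the category-partition property runs
1000 small cohorts (n = 30–80); type-I error uses 1000 null replicates at
n = 500 (standard-error ≈ 0.7 pp at the 5% level); calibration quality was
assessed at n = 30000 during development.

## Known limitations

* Sex is binary throughout, as in the sex-stratified equations the method
  is built on; records with missing sex are excluded from sex-stratified
  derivations and counted.
* The exhaustion component follows the literal all-items-observed rule; a
  participant with one positive and one missing item is unable-to-score
  on that domain even though the observed item would suffice for
  positivity.  This matches the strict reading of the missing-data rule;
  the alternative is a one-line change in `component_flags()` if a future
  convention settles it.
* The wealth index is a relative, within-cohort construct; scores and
  quintiles are not comparable across cohorts scored separately.
* Single-wave (cross-sectional) schema only; no longitudinal linkage.
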