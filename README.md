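# phenofrail

Phenotypic (Fried-type) frailty scoring and its correlates for
cross-sectional cohort studies of middle-aged and older adults, with the
derivation conventions used in population studies where external normative
cutoffs are unavailable: cutoffs are *derived from the cohort itself* as
sex-specific quintiles of covariate-adjusted physical performance.

The package is aimed at epidemiologists and biostatisticians who need a
tested, reproducible implementation of the whole chain from raw field
measurements to association tables — including the parts that are easy to
get subtly wrong: trial aggregation rules, strict-versus-non-strict
inequalities at every threshold, missing-data propagation, quantile
definitions, and half-up rounding of published percentages.

## The score

Five binary domains, one point each:

| domain | rule |
|---|---|
| weight loss | self-reported loss > 4 kg over the last year |
| exhaustion | either of two CES-D items at "3–4 days a week" or more often |
| low grip | BMI-adjusted maximum grip < sex-specific 20th percentile |
| low walk | height-adjusted 4 m walk speed < sex-specific 20th percentile |
| low activity | self-reported sitting hours ≥ sex-specific 80th percentile |

Grip is the maximum of up to four trials (two per hand); walk speed is
4 m divided by the fastest of two timed walks.  Adjustment is linear about
a sex-stratum reference value, `adjusted = raw − (covariate − ref) · slope`,
with the slope fitted by ordinary least squares within the stratum
(derive mode) or supplied as a fixed published equation (fixed mode).

Score 0 = non-frail, 1–2 = prefrail, ≥3 = frail; any missing domain makes
the participant *unable to score* (an explicit fourth category, analysed
separately or merged with frail as a sensitivity coding).

Around the score the package provides rule-based hypertension, diabetes
and ADL-impairment classifiers; an asset-based wealth index (first
principal component of the polychoric correlation matrix, in quintiles);
and the association battery: Pearson chi-squared with a Fisher-exact
switch at any cell ≤ 5, Mantel–Haenszel linear trend, Student
t/Mann–Whitney contrasts, and crude/age-sex-adjusted logistic odds ratios
under both frailty codings.  A calibrated synthetic cohort generator makes
every stage testable end to end without access to restricted field data.

## Worked example

```r
library(phenofrail)

coh <- generate_cohort(cohort_config(n = 1000, seed = 7))
fit <- frailty_fit(coh)        # derive-mode cutoffs + scores
fit
#> Phenotypic frailty fit (derive-mode cutoffs), n = 1000
#>   non_frail          403 (40.3%)
#>   prefrail           458 (45.8%)
#>   frail               67 (6.7%)
#>   unable_to_score     72 (7.2%)

coef(fit)                      # the derived cutoffs
#>        grip_male      grip_female        walk_male      walk_female
#>       35.8028326       25.6585967        0.7813181        0.7221644
#>     sitting_male   sitting_female   weight_loss_kg exhaustion_level
#>       34.7154034       37.6637421        4.0000000        2.0000000

y   <- frailty_outcome(fit$scores$category, "frail_only")
hyp <- classify_hypertension(coh, fit$performance)$hypertension
adjusted_or(y, hyp, data.frame(age = coh$age, sex = coh$sex))
#> logistic (adjusted) (n = 917)
#>  level   or conf_low conf_high      p estimable
#>    yes 1.69    0.947      3.03 0.0754      TRUE
```

The category percentages partition the cohort; the grip/walk cutoffs sit
at the sex-specific 20th percentiles of the adjusted distributions (so the
corresponding component prevalences are 20% by construction among
participants with the measure observed); and the adjusted odds ratio is the
hypertension–frailty association after age and sex adjustment, here at
n = 1000 with a correspondingly wide Wald interval.  `run_pipeline()`
produces the full set of publication-style tables
(`write_bundle()` writes them as CSV/JSON), `predict()` carries derived
cutoffs to a new cohort, and `reference_cutoffs()` /
`reference_adjustments()` hold the fixed published equation set for
fixed-mode scoring.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and its
conventions in full: the quantile definition and its effect on cutoffs,
every boundary rule, the missing-data semantics, the wealth-index
estimator, what the synthetic generator does and does not emulate, and the
package's design decisions on the points the source conventions leave
open.
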