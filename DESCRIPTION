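Package: phenofrail
Title: Phenotypic Frailty Scoring and Correlates for Cross-Sectional Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives the Fried phenotypic frailty score from raw physical
    performance and self-report data: trial aggregation (maximum grip,
    fastest 4-metre walk), sex-specific covariate adjustment of grip (for
    body mass index) and walk speed (for height), sex-specific quintile
    cutoffs, five component flags with explicit missing-data semantics, and
    the non-frail/prefrail/frail/unable-to-score categories. Also provides
    rule-based hypertension, diabetes and activities-of-daily-living
    classifiers, an asset-based wealth index via polychoric principal
    components, the accompanying association battery (chi-squared with a
    Fisher exact switch, Mantel-Haenszel linear trend, crude and
    age/sex-adjusted logistic odds ratios under two frailty codings), a
    calibrated synthetic cohort generator for end-to-end testing, and a
    report pipeline producing publication-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
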