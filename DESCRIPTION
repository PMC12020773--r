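Package: chronomtp
Title: Meal-Timing Patterns and Metabolic Outcomes with Measurement-Error Correction
Version: 0.1.0
Authors@R:
    person("BIPS", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives meal-timing exposures (morning and evening energy
    proportions, eating window, pre-sleep fasting, eating frequency) from
    meal-level 24-hour dietary recall records, estimates usual (error-free)
    exposures with a transformed linear mixed error model in the spirit of the
    NCI method, clusters participants into meal-timing patterns by k-means on
    standardised usual exposures, and estimates pattern-outcome associations
    with a multiple-imputation three-stage procedure pooled by Rubin's rule.
    Includes a single-exposure best-subset analysis with cluster-bootstrap
    confidence intervals, a synthetic cohort generator emulating the
    statistical structure of a multi-country child cohort, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
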