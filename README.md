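# chronomtp

Meal-timing patterns and metabolic outcomes in children, with measurement-error
correction.

## Who this is for

Nutritional epidemiologists analysing repeated 24-hour dietary recalls
(24HDR) against metabolic outcomes. A single recall day is an error-prone
snapshot of a child's usual eating rhythm; analyses that cluster children on
single-day values and regress outcomes on the clusters suffer both classical
attenuation and cluster-misclassification bias. `chronomtp` implements the
corrected workflow end to end, plus a synthetic cohort generator so every
stage is testable without access to individual-level data.

## What it computes

From meal-level recall records (occasion clock time, energy, healthy flag,
wake/bed times) it derives five daily exposures — energy proportion in
[05:00, 11:00) and [17:00, 24:00), eating window, pre-sleep fasting, eating
frequency — applies a < 500 kcal day exclusion and Goldberg EI/BMR
plausibility flags, then runs a **three-stage** analysis:

1. **Usual exposures** (NCI-style): per component, a Box–Cox transformed
   linear mixed model
   `g_λ(y_ij) = x_ij'β + u_i + ε_ij` with person random intercept;
   regression-calibration BLUPs with second-order back-transform bias
   correction and 5/7 : 2/7 weekday/weekend weighting.
2. **Meal-timing patterns (MTPs)**: k-means (k = 3) on the z-scores of the
   usual exposures; centroids frozen and named *early-often*, *late-long*,
   *late-infrequent-short* by their signatures.
3. **Association with multiple imputation**: an outcome-conditioned error
   model generates M conditional draws of each child's usual exposures; each
   draw is classified with the frozen Stage-2 function and a linear mixed
   model (outcome z ~ MTP + age + BMI z + ISCED + sex + country, family
   random intercept) is fitted; estimates are pooled by Rubin's rule
   (`T = W + (1 + 1/M)B`, t-based CIs).

A complementary single-exposure analysis does exhaustive best-subset
selection (31 subsets, BIC, covariates fixed) with family-cluster bootstrap
percentile CIs. HOMA-IR (`insulin·glucose/22.5`), sleep duration
(`2/7·(WE) + 5/7·(WD)`), Schofield BMR and age/sex outcome standardisation
are provided as building blocks.

## Worked example

```r
library(chronomtp)

spec   <- population_spec(n_participants = 600, seed = 2024)
cohort <- simulate_cohort(spec)
daily  <- derive_daily_exposures(cohort$meals)
daily  <- label_plausibility(daily, cohort$participants)
table(daily$plausibility)
#> misreporter   plausible
#>         210         820

res <- run_three_stage(daily, cohort$participants, cohort$outcomes,
                       outcome = "homa_ir_z", M = 50, seed = 2024)
res$mtp_model
#> Meal-timing pattern model (k = 3 )
#>                       morning_pct evening_pct window_h fasting_h frequency
#> early-often                  0.91       -0.87     0.23     -0.88      0.80
#> late-infrequent-short       -0.58        0.60    -1.07      1.05     -0.95
#> late-long                   -0.41        0.36     0.57      0.04     -0.04
#> inertia: 1585.8

res$results[, c("contrast", "beta", "ci_lower", "ci_upper", "M")]
#>                contrast  beta ci_lower ci_upper  M
#> 1 late-infrequent-short 0.266   -0.035    0.567 50
#> 2             late-long 0.160   -0.131    0.451 50
```

The centroid table is the standardised signature of each pattern: the
*early-often* cluster eats a large share of its energy in the morning
(z = 0.91), often (z = 0.80) and goes to bed soon after the last meal
(fasting z = −0.88); *late-infrequent-short* is its mirror image. The pooled
contrasts say that in this simulated cohort (true contrasts 0.06 and 0.19)
children in the *late-infrequent-short* pattern have a 0.27 higher HOMA-IR
z-score than *early-often* children, with a Rubin 95% CI reflecting both
sampling and imputation uncertainty at n = 600.

One full pipeline run (simulate → derive → usual → cluster → associate →
select, with artifacts, config snapshot and a deterministic log):

```r
run_full_pipeline(default_config(out_dir = "run1", seed = 1,
                                 n_participants = 600, M = 50, B = 200))
```

or from the shell:

```sh
Rscript inst/cli/chronomtp.R run-all --out-dir run1 --seed 1 --M 50 --B 200
```

## Layout

- `R/` — generator (`synthetic_cohort.R`), exposure derivation
  (`recall_processing.R`), usual-intake model (`usual_exposure_model.R`,
  closed-form random-intercept engine in `ranint.R`), clustering
  (`mtp_clustering.R`), MI association (`mi_association.R`), best-subset
  selection (`exposure_selection.R`), pipeline/CLI (`pipeline.R`).
- `vignettes/meal-timing-patterns.Rmd` — the methods vignette: model,
  assumptions, tunables, what the generator does and does not emulate,
  numerical choices, limitations.
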