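---
title: "Meal-timing patterns, measurement error and the three-stage analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meal-timing patterns, measurement error and the three-stage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomtp)
```

## The scientific problem

Chrono-nutrition asks whether *when* children eat — not only what or how
much — matters for metabolic health. From repeated 24-hour dietary recalls
(each recall records every eating occasion of the previous day with its
clock time and energy), five daily exposures are derived per recall day:

* **morning energy proportion** — % of the day's energy eaten in
  [05:00, 11:00);
* **evening energy proportion** — % eaten in [17:00, 24:00);
* **eating window** — hours between the first and last occasion;
* **pre-sleep fasting** — hours between the last occasion and bedtime;
* **eating frequency** — number of eating occasions.

A single recall day is an error-prone measurement of a child's *usual*
behaviour: day-to-day variation is large, and in typical cohorts half the
children contribute only one recall. Clustering children on single-day
values and regressing outcomes on the clusters therefore suffers both
classical attenuation and cluster-misclassification bias. This package
implements the full corrected analysis:

1. **Stage 1 — usual exposures.** A measurement-error ("usual intake")
   model in the spirit of the NCI method: each exposure component is
   modelled on a Box–Cox transformed scale with a person random intercept,

   $$g_\lambda(y_{ij}) = x_{ij}^\top\beta + u_i + \epsilon_{ij},\qquad
     u_i \sim N(0,\sigma_u^2),\ \epsilon_{ij} \sim N(0,\sigma_\epsilon^2),$$

   with covariates sex (and sex-by-covariate interactions, the single-fit
   equivalent of sex-stratified models), a weekend indicator, age, parental
   education (ISCED) and BMI z-score. The regression-calibration (RC)
   prediction of a person's usual value is the BLUP
   $\hat u_i = \frac{\sigma_u^2}{\sigma_u^2 + \sigma_\epsilon^2/n_i}\,
   \bar r_i$ added to the covariate prediction, back-transformed with a
   second-order Taylor correction for within-day error
   ($g^{-1}(t) + \tfrac12 g^{-1\prime\prime}(t)\,\sigma_\epsilon^2$) and
   combined over the week as $5/7$ weekday $+\,2/7$ weekend.
2. **Stage 2 — patterns.** k-means (Lloyd, k-means++ seeding, best of 25
   starts) on the z-scores of the RC usual exposures, $k = 3$. Centroids are
   named by their signature: maximal morning-energy z → *early-often*; of
   the rest, minimal eating-window z → *late-infrequent-short*; the other →
   *late-long*. The standardisation parameters and centroids are **frozen**
   as the classification function.
3. **Stage 3 + MI loop — association.** A second Stage-1 model set is
   fitted that additionally conditions on the outcome z-score (proper
   imputation). For each of $M$ imputations, each person's random effect is
   drawn from its conditional posterior
   $N(\hat u_i, (1/\sigma_u^2 + n_i/\sigma_\epsilon^2)^{-1})$, the drawn
   usual exposures are classified with the frozen Stage-2 function, and a
   linear mixed model of the outcome z-score on pattern membership (plus
   covariates, family random intercept for siblings) is fitted. The $M$
   contrast estimates are pooled by Rubin's rule:
   $\bar\beta$, $W$ (mean variance), $B$ (variance of estimates),
   $T = W + (1+1/M)B$, $df = (M-1)(1 + W/((1+1/M)B))^2$,
   CI $= \bar\beta \pm t_{df}\sqrt T$.

A complementary single-exposure analysis performs exhaustive best-subset
selection over the five usual exposures (covariates fixed, BIC on ML
mixed-model fits, REML refit of the winner) with family-cluster bootstrap
percentile CIs.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| low-energy exclusion | 500 | kcal/day | implausibly low recall days are removed (strictly below) |
| clock windows | [05:00, 11:00), [17:00, 24:00) | — | half-open avoids double counting; post-midnight intake is outside both (config switch) |
| Goldberg cutoffs | (1.05, 2.28) | EI/BMR | common paediatric adaptation; constants are configuration |
| Schofield constants | sex- and age-band-specific | kcal/day | BMR for the Goldberg ratio; affine in weight |
| Box–Cox grid | {0, 0.25, 0.5, 0.75, 1} | — | profile-ML selection, ties toward 1 (less transformation) |
| k, starts | 3, 25 | — | three interpretable patterns; restarts guard against bad local optima |
| M | 500 (tests: 50) | imputations | analysis default; tests are scaled down for runtime and say so |
| B | 1000 | bootstrap reps | percentile CIs for selected coefficients |
| weekday/weekend weights | 5/7, 2/7 | — | same convention as the sleep-duration formula |

## What the synthetic cohort emulates — and what it does not

No individual-level data ship with the package; the generator *states a
world* with the statistical structure the analysis assumes:

* three latent archetypes (*early-often*, *late-long*,
  *late-infrequent-short*) whose mean z-score signatures and mixing weights
  (0.360 / 0.373 / 0.267) follow the reported field values;
* population exposure means/SDs of 25.5 (5.8) %, 35.8 (4.3) %, 11.5 (0.6) h,
  2.5 (0.4) h, 4.16 (0.4) occasions;
* repeated-recall availability 49.4% / 27.3% / 23.3% for 1 / 2 / ≥3 recalls
  (≥3 realised as 3);
* within-person day-to-day error with SD 0.75 × the population SD per
  exposure (a within:between variance ratio near 1; no reference value exists
  for this ratio, so it is an explicit modelling choice exposed in
  `population_spec()`);
* person-level spread around the archetype mean of 0.45 SD on the z scale.
  This makes the archetypes *well separated* (planted-partition recovery is
  meaningful) at the cost of marginal exposure SDs about 20–35% below the
  published values — the two requirements are mutually exclusive given the
  published centroid separations, and separation was chosen;
* energy as a person-level usual EI/BMR ratio (mean 1.18, SD 0.12) plus
  day-level noise (SD 0.15), kept inside the Goldberg interval, with a 20%
  rate of injected low-energy misreported days (EI/BMR ~ U(0.55, 1));
* sibling pairs (30% of children) sharing family id, country, ISCED and a
  family random intercept in the outcomes;
* mild archetype–covariate confounding (the "late" patterns are older and
  heavier), so covariate adjustment genuinely matters;
* outcome contrasts vs *early-often* of published magnitude (HOMA-IR z:
  +0.06 / +0.19; HbA1c z: −0.02 / −0.02; triglycerides z: +0.02 / +0.05).

Each recall day is constructed *backwards* from its exposure targets:
breakfast-like first occasion inside the morning window, dinner-like last
occasion inside the evening window, intermediate occasions between them, and
occasion energies solved so the derived exposures reproduce the targets
exactly (menus carry no information in this analysis — the exposures do).
Misreported days rescale total energy only, which leaves every proportion,
time and count untouched.

**Not emulated:** food items and nutrients, country-specific food
composition, accelerometry, reporting heterogeneity beyond the single
misreport mechanism, seasonal effects, and any non-Gaussian person-level
structure beyond the three-component mixture. A green test therefore
establishes that the *estimators* behave correctly in a world with the
assumed error structure — not that the assumptions hold in any real cohort.

## Numerical choices

* **Mixed-model engine.** Both Stage 1 and Stage 3 need only a single
  random intercept, for which GLS has a closed Sherman–Morrison form per
  group; the package profiles $\beta$ and $\sigma^2$ out and optimises the
  variance ratio in one dimension. This is exactly the REML/ML solution (the
  test suite checks coefficients, SEs, variance components, log-likelihoods
  and BLUPs against `lme4::lmer` to optimizer precision) and is what makes a
  500-imputation loop affordable. `engine = "lmer"` is available throughout.
* **Eating frequency is a count.** Day-level frequency is the rounded
  target (min 3 occasions so all three windows are realisable). Rounding is
  genuine quantisation noise: usual frequency is the hardest exposure to
  recover from one or two recalls, which is visible in planted-recovery
  results.
* **Back-transform.** Second-order Taylor bias correction; the Box–Cox
  argument is clamped away from zero before inversion.
* **Degenerate inputs.** Bedtime before the last occasion flags the day and
  sets fasting missing (no clipping). Proportions from usual-kcal ratios are
  clamped to [0, 100] after the ratio. A singular family random effect falls
  back to zero family variance. Equidistant centroid assignment resolves to
  the lowest centroid index; pattern-name ties break on the evening-energy
  z-score.
* **Seeding.** Every stochastic function takes a seed and restores the
  caller's RNG state; one pipeline seed fans out to stage seeds through a
  fixed integer rule, so a rerun of the same configuration is byte-identical.

## Open design decisions taken

* Exposures are modelled **univariately** in Stage 1; cross-exposure
  dependence enters through shared covariates only (a Gaussian copula on the
  person-effect posteriors was considered and left out, because the joint
  distribution of the five usual exposures is not identifiable from one to
  three recalls without strong assumptions).
* Proportions are modelled on the **window-energy (kcal) scale** and turned
  into percentages as the ratio of usual window energy to usual total
  energy, not modelled directly as percentages.
* Misreporters are **retained** in the main analysis (BMI z adjusts for
  them); the plausible-reporters subsample is a sensitivity switch. A
  participant is a misreporter when at least half of their retained days are
  flagged.
* The bootstrap resamples **families**, not individuals (the model carries
  a family random intercept); individual resampling is a switch.
* BIC is the selection criterion — consistent for a fixed candidate set
  and conservative against over-selection; AIC and a Mallows-style option
  sit behind a flag.
* Rubin degrees of freedom use the classical large-sample formula;
  Barnard–Rubin is available by flag.
* The outcome-conditioned Stage-1 fits are **per outcome**: each outcome
  gets its own imputation model, which keeps the conditioning correct for
  the model actually fitted in Stage 3.

## Known limitations

* With one recall for half the cohort, shrinkage toward the covariate mean
  is strong; usual-exposure estimates for one-recall children carry most of
  the residual misclassification.
* The Stage-1 random effect is modelled as Gaussian while the generating
  truth is a three-component mixture; the MI correction is nevertheless
  nearly unbiased in the simulated world (see the acceptance suite), but no
  claim is made for heavier misspecification.
* The naming rule is defined for $k = 3$ only; other $k$ get generic names.
* Percentile bootstrap CIs are reported without bias correction (BCa was
  judged unnecessary at these sample sizes).
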