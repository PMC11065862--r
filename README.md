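# bioagedr

Biological-age clocks and survey-weighted risk models for diabetic
retinopathy.

People of the same chronological age (CA) can age biologically at very
different rates, and that variation — not the calendar — appears to drive
much of the risk of diabetic retinopathy (DR), the leading preventable cause
of working-age blindness. `bioagedr` implements the full analysis pipeline
for testing that hypothesis on NHANES-style examination data: two
clinical-biomarker aging clocks, the cohort-derivation rules that define the
analytic sample, design-based survey statistics for complex multistage
samples, restricted-cubic-spline dose–response curves, and ROC /
decision-curve evaluation — together with a synthetic cohort generator with
a latent aging process and known effect sizes, so every stage can be
validated against ground truth without any data download.

## The estimators

**Klemera–Doubal biological age (BA).** Each of 8 biomarkers (ln CRP,
creatinine, HbA1c, albumin, total cholesterol, urea nitrogen, alkaline
phosphatase, systolic BP) is regressed on CA in a training sample, giving a
slope *k*, intercept *q*, RMSE *s* and variance explained *r²* per marker.
The biomarker-only estimate is the precision-weighted average

    BA_E = Σⱼ (xⱼ − qⱼ)(kⱼ/sⱼ²) / Σⱼ (kⱼ/sⱼ)²

and the final estimate shrinks BA_E toward CA,

    BA = [Σⱼ (xⱼ − qⱼ)(kⱼ/sⱼ²) + CA/S_BA²] / [Σⱼ (kⱼ/sⱼ)² + 1/S_BA²],

where S_BA² is estimated from the training sample through the
characteristic correlation coefficient r_char. BA is always a convex
combination of BA_E and CA.

**Phenotypic Age (PA).** A fixed, published linear predictor `xb` over 9
blood biomarkers plus CA, mapped to the age scale through a
mortality-hazard (Gompertz) transform. The printed nested transform
collapses algebraically to an affine function of `xb`; the affine form is
used for computation because the nested form underflows in double
precision (see the methods vignette).

**Age acceleration** is the indicator BA > CA (or PA > CA).

Risk models are survey-weighted logistic regressions with
Taylor-linearized (between-PSU sandwich) variance, t-based inference on
design degrees of freedom, a Model-1/2/3 covariate ladder, Rao–Scott
second-order corrected chi-squared descriptive tests, 3-knot restricted
cubic splines, and ROC/DCA model evaluation.

## Worked example

```r
library(bioagedr)

sim <- simulateCohort(simConfig(n_subjects = 2000), seed = 11)
d <- deriveCohort(sim$cohort)          # DM/DR status, averaged BP, HOMA-IR
clock <- kdmTrain(d, c("ln_crp", "creatinine", "hba1c", "albumin",
                       "total_cholesterol", "urea_nitrogen", "alk_phos", "sbp"))
clock
#> Klemera-Doubal clock: 8 biomarkers, trained on n = 2000
#>   CA range: 40.03367 - 84.98513 years
#>   r_char = 0.3622  S_BA^2 = 35.35 years^2

d$ba <- kdmScore(d, clock)$ba
d$pa <- phenoageScore(d)
head(round(data.frame(ca = d$ca, ba = d$ba, pa = d$pa), 1), 4)
#>     ca   ba   pa
#> 1 49.6 48.7 37.7
#> 2 81.1 85.4 83.4
#> 3 60.8 55.6 51.4
#> 4 48.7 45.6 41.1

design <- surveyDesign(d$stratum, d$psu, d$weight)
modelSuite(d, design, "pa")            # crude / demographics / fully adjusted
#>    model exposure term       or       lo       hi            p
#> 1 model1       pa   pa 1.144135 1.107743 1.181722 2.331973e-07
#> 2 model2       pa   pa 1.246160 1.169819 1.327482 2.148858e-06
#> 3 model3       pa   pa 1.248304 1.172201 1.329348 1.843473e-06
```

Each year of Phenotypic Age carries a 14% higher odds of DR in the crude
model (24% fully adjusted) in this simulated cohort, while the same cohort
gives `auc_pa = 0.880` versus `auc_ca = 0.807` from
`comparePredictors(d, design, c("pa", "ca"))` — the aging clock reads the
biomarker signal that actually drives DR in the generator, chronological
age only its correlate.

The end-to-end pipeline (exclusion flow, weighted descriptives, OR ladder
for BA/PA/CA and the acceleration flags, spline curves, ROC/DCA, subgroup
and sensitivity tables, manifest) runs as:

```r
res <- runPipeline(runConfig(sim_config = simConfig(), outdir = "out", seed = 1))
```

or from a shell via `inst/scripts/run_pipeline.R`. File-based cohorts use
the column dictionary in `cohortColumns()`.

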