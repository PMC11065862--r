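---
title: "Methods: aging clocks, design-based inference, and the synthetic cohort"
author: "bioagedr"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bioagedr)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the numerical choices that were genuinely
open, and what the synthetic-data experiments do and do not demonstrate.

# The two aging clocks

## Klemera–Doubal biological age

The estimator assumes each biomarker is, in the training population, a
linear function of age with homoscedastic Gaussian noise. We follow the
classical construction literally:

1. regress each biomarker **on chronological age** (not the inverted
   regression used by some variants) and keep slope $k_j$, intercept
   $q_j$, RMSE $s_j$ (divisor $n$) and variance explained $r_j^2$;
2. form the biomarker-only estimate
   $BA_E = \sum_j (x_j - q_j)(k_j/s_j^2) \big/ \sum_j (k_j/s_j)^2$;
3. summarize marker–age correlation as
   $r_{char} = \left[\sum_j r_j^2/\sqrt{1-r_j^2}\right] \big/
   \left[\sum_j r_j/\sqrt{1-r_j^2}\right]$ with $r_j = +\sqrt{r_j^2}$;
4. estimate the age-shrinkage scale
   $S_{BA}^2 = \mathrm{Var}_n(BA_E - CA) -
   \frac{1-r_{char}^2}{r_{char}^2}\cdot\frac{(CA_{max}-CA_{min})^2}{12m}$
   and compute the final
   $BA = \left[\sum_j (x_j-q_j)k_j/s_j^2 + CA/S_{BA}^2\right] \big/
   \left[\sum_j (k_j/s_j)^2 + 1/S_{BA}^2\right]$.

Numerical and interpretive choices:

* **Index mixing in the scale formula.** The printed inner mean mixes the
  subject indices of $BA_E$ and $CA$; we read it as the per-subject
  deviation $(BA_{E,i} - CA_i)$ centered at its own mean — the only
  reading under which the quantity is a variance. This is flagged here
  rather than silently assumed elsewhere.
* **Floors.** $s_j$ below $10^{-8}\times\mathrm{SD}(x_j)$ raises a
  degenerate-fit error naming the biomarker (a near-interpolating
  regression would otherwise dominate the precision weights); a
  non-positive $S_{BA}^2$ — which occurs legitimately when markers track
  age weakly and $m$ is small — is floored at $10^{-6}\,\mathrm{y}^2$
  with a warning, which collapses BA onto CA rather than producing a
  negative variance.
* **Signs.** Markers that fall with age keep their negative $k_j$; the
  signs cancel in numerator and denominator, which the suite checks with
  a falling-marker recovery test.
* **Training sample and weights.** Training defaults to the analytic
  sample with unweighted least squares; survey-weighted training is
  available (`weights =`) since the choice is not determined by the
  method. Both paths are tested.
* Useful identities that the tests pin down: for $m = 1$,
  $BA_E = (x-q)/k$ independent of $s$; markers lying exactly on their
  regression lines at age $a$ return $BA_E = a$; BA is always a convex
  combination of $BA_E$ and CA.

## Phenotypic Age

PA is a fixed, published linear score `xb` over nine blood biomarkers plus
CA (units matter: albumin g/L, creatinine µmol/L, glucose mmol/L, CRP as
ln(mg/dL), ALP U/L, WBC 10³ cells/µL), pushed through a Gompertz
mortality transform. The printed nested transform
$141.50 + \ln\!\left[-0.00553\,\ln\!\big(e^{-1.51714\,e^{xb}/0.0076927}\big)\right]/0.09165$
is algebraically an affine function of `xb`:
$141.50 + (xb + \ln(0.00553 \cdot 1.51714/0.0076927))/0.09165$,
because the ten-year-risk nonlinearity cancels exactly. Whether the
affine collapse was intended by the original construction cannot be
determined from the printed equation alone; we implement what is printed.
The affine form is the computational path: the naive nested evaluation
underflows for $xb \gtrsim 1$ and suffers catastrophic cancellation in
$\ln(e^w)$ for $|w| \lesssim 10^{-7}$ (i.e. $xb \lesssim -19$), so it
serves as a test oracle only inside its double-precision validity band,
with the inner $\ln\circ\exp$ evaluated exactly outside it. One
consequence the tests assert to $10^{-9}$: PA rises by exactly
$0.0804/0.09165 \approx 0.877$ years per year of CA at fixed biomarkers.

CRP must be positive before taking the log; non-positive CRP is an input
error rather than a clamp — failing loudly beats silently shifting a
skewed marker. Missing inputs are likewise errors listing the missing
names: an aging score computed from a partial panel is not the same
score.

# Cohort derivation

Boundary semantics follow the printed wording literally: HbA1c **strictly
above** 6.5%; fasting glucose ≥ 7.0 mmol/L; random/2-h OGTT ≥ 11.1
mmol/L; hypertension at ≥ 140 systolic **or** ≥ 90 diastolic. Whether
"random/2-h OGTT" is one field or two is unspecified; the classifier
accepts either and ORs them. DR is defined only among DM — lesions in a
non-diabetic subject never count — with the ungradable eye imputed from
the gradable one and the person-level grade taken as the worse eye (for a
binary lesion flag, worse-eye and either-eye logic coincide).

Blood-pressure averaging applies two printed rules whose order is not
printed; we document one order and test it: drop the first reading (when
there are several), then drop zero-diastolic readings from the remainder;
if that empties the set, fall back to all readings minus zero-diastolic
ones, and finally to the post-first set unchanged.

The exclusion cascade removes records at the **earliest** failing step
(imaging/biomarkers, then demographics, then other covariates), so the
per-step counts are order-dependent by construction and always reconcile:
removed + remaining = input.

# Design-based inference

The R package ecosystem's standard survey tooling is not a dependency
here; the estimators are implemented directly and validated against
independent oracles (ordinary `glm` under equal-weight iid designs,
brute-force linearization formulas, permutation calibration).

* **Variance.** Taylor linearization throughout: the covariance of any
  estimator is the stratified between-PSU covariance of its linearized
  per-record contributions, with the $n_h/(n_h-1)$ stratum factor.
  Replicate-weight methods are out of scope.
* **Lonely PSUs.** A stratum contributing a single PSU is centered at the
  grand mean of all PSU totals (the common "adjust" convention), with a
  warning — the choice is a documented knob, not a silent default.
* **Reference distribution.** Wald tests and CIs use a t reference with
  the conventional design degrees of freedom (#PSUs − #strata); joint
  Wald tests use F(q, df). With 30 PSUs this matters.
* **Logistic fits.** Weighted maximum pseudo-likelihood by Newton/IRLS;
  non-convergence, coefficients beyond ±30, or fitted probabilities that
  reproduce the outcome to $10^{-6}$ (perfect separation) are explicit
  errors with diagnostics. Two invariances are tested: splitting any
  record into half-weight copies in the same PSU, and rescaling all
  weights by a constant, change nothing.
* **Rao–Scott.** The descriptive chi-squared uses the second-order
  (Satterthwaite) correction: the design-weighted Pearson statistic is
  referred to a scaled $\chi^2$ whose scale $\sum d_k^2/\sum d_k$ and df
  $(\sum d_k)^2/\sum d_k^2$ come from the eigenvalues $d_k$ of the
  generalized design-effect matrix on the interaction-contrast space.
  Under an equal-weight iid design the statistic reduces to classical
  Pearson and the p-values are uniform under independence (checked by a
  KS test over 500 simulated tables).
* **Model ladder.** Model 1 crude; Model 2 adds age, sex,
  race/ethnicity, PIR, marital status, education; Model 3 adds physical
  activity, HEI-2015, drinking, smoking, BMI, CVD history, hypertension.
  When the exposure is CA itself, age is omitted from the covariates.
  Trend tests refit with ordinal level codes 0, 1, 2 as a continuous
  term; interaction tests jointly Wald-test the cross-product terms.
  Subgroup fits drop the stratifying variable from the covariates and
  return flagged rows (never errors) for degenerate cells.

**Small-cluster behavior.** With ~30 PSUs, the sandwich estimator is
known to run slightly anti-conservative in small subsamples: in a
DM-restricted null fit (~190 subjects) the mean estimated SE is ~14%
below the true sampling SD and the nominal 5% test rejects at ~8%. On
full cohorts of n = 1000 the permuted-outcome null rejects at 4–5%. This
is a property of Taylor-linearized variance at few clusters, shared by
standard survey software, and is why the package's calibration
experiment is defined on the full-cohort null.

# Splines, ROC and decision curves

Three knots at the 10th/50th/90th weighted percentiles (weighted
quantiles interpolate the midpoint-mass CDF; unweighted quantiles are the
standard type-7 definition). The basis is Harrell's restricted
truncated-power basis normalized by $(k_3-k_1)^2$ — one nonlinear column
for 3 knots, zero below the first knot, exactly linear above the last.
OR curves are anchored at the weighted median by default (configurable);
the curve at the reference is identically 1 with a zero-width band, and
the whole curve is invariant to affine rescaling of the exposure. The
nonlinearity p-value is the Wald test of the single nonlinear
coefficient: uniform under a linear logit, and detecting a threshold
logit at n = 4000 in over 90% of replicates.

AUC is the Mann–Whitney concordance (ties at ½), identical to the
trapezoidal area and verified exactly against an exhaustive
pair-counting oracle on every fixture up to 200 records; the weighted
variant replaces pair counts with weight products. Net benefit is
$TP/n - FP/n \cdot p_t/(1-p_t)$ on a 0.01–0.99 grid (step 0.01);
treat-all crosses zero exactly at the prevalence. Whether the published
analyses weighted these curves is unstated, so both modes exist and the
default is unweighted; likewise ROC can score raw exposures or
Model-3-adjusted predicted probabilities (default: model probabilities).
AUC confidence intervals and DeLong-type comparisons are out of scope.

# The synthetic cohort generator

The generator is first-class, tested code. It emulates:

* a stratified multistage design (default 15 strata × 2 PSUs), lognormal
  weights scaled to a pseudo-population (default 20n) — ignorable by
  default, with an outcome-correlated option for stress tests;
* latent biological age $B = CA + \Delta$, $\Delta \sim N(0, 5^2)$ years,
  independent of CA — five years being the realistic scale of
  clinical-clock deviations in adult examination cohorts;
* biomarkers as independent Gaussian noisy linear functions of $B$
  (log-CRP simulated directly on the log scale), with physiologic
  intercepts/slopes anchored at age 60; blood pressure gets a
  person-level set point so that hypertension is a non-degenerate
  covariate;
* dysglycemia as a latent liability rising with $B$, shifting glucose and
  HbA1c so that DM classification (through the same rules as real data)
  yields ~19% DM, and DR assigned **only within DM** by a logistic model
  in $B$ (designed OR 1.11/year by default) whose intercept is solved so
  the DM-subset DR prevalence is 27.1% — matching the study conditions
  of the population the pipeline targets (~5% DR overall);
* covariates as simple categorical draws with configurable DR effects,
  defaulting to **null** so the designed exposure OR is exactly the
  crude-model estimand.

A single run seed feeds a documented per-stage substream scheme
(stage $k$ re-seeds at $101\,s + k$), so adding a stage never perturbs
earlier draws; identical (config, seed) pairs are byte-identical.

What the generator does **not** emulate: NHANES nonresponse adjustment or
poststratification, real biomarker marginals or correlations between
biomarker noise terms, item missingness (the exclusion cascade is
exercised on constructed fixtures), or direct covariate effects on DR by
default. Passing tests therefore demonstrate the estimators' correctness
and calibration under a known, well-specified data-generating process —
not robustness to the messiness of real survey data.

## The recovery and attenuation experiments

Because DR is generated only within DM, the designed per-year OR is the
estimand of the **DM-restricted crude fit** on true latent age: within
DM, DR depends on nothing but $B$ (selection into DM depends on $B$ but
not additionally on DR), so that fit is consistent. A full-cohort fit
would convolve the DR model with DM selection and has no designed value.
Across 200 cohorts of n = 2000 the mean fitted OR is ~1.111 against the
designed 1.11, with design-based 95% CI coverage ~93%.

The CA-only fit is attenuated toward 1 relative to the latent-age fit,
but mildly: with $\Delta$ independent of CA, $E[B\,|\,CA] = CA$ with
slope one, so attenuation arises only from logistic-normal
marginalization over $\Delta$ and from the DM-selection collider (within
DM, higher CA needs less $\Delta$), together worth ~0.005 on the OR at
these settings — real but smaller than the per-replicate estimation
noise (SD ≈ 0.02). The attenuation contrast is therefore a property of
**replicate means**, not of individual replicates, and that is how the
suite asserts it. The sharp BA/PA-versus-CA contrast seen in real
cohorts reflects additional structure (biomarkers mechanistically linked
to the outcome) that the clocks capture and CA cannot.

Problem sizes used by the simulation studies — 200 replicates of
n = 2000 for recovery, 500 of n = 1000 for calibration, 500 simulated
tables for the Rao–Scott uniformity check — were chosen to make
Monte-Carlo error comfortably smaller than the property bands being
asserted while keeping the default suite quick to run.

# Pipeline and interfaces

`runPipeline()` drives the whole analysis from a config object
(synthetic or file input), writing each artifact as a delimited table —
exclusion flow, weighted descriptives with Rao–Scott p-values, the
Model-1/2/3 ladder for BA/PA/CA and both acceleration flags, the CA
category trend test, spline curves, ROC/DCA tables, subgroup tables with
interaction p-values, the DM-restricted and insulin/HOMA-IR-adjusted
sensitivity analyses — plus a manifest with content hashes, the seed and
the package version. Reruns with the same seed are byte-identical.
Validation is fail-fast: a missing column or unknown exposure aborts
before any computation. The exported functions are the primary
interface; `inst/scripts/run_pipeline.R` is a thin shell wrapper.

# Known limitations

* Replicate-weight variance, multiple imputation, penalized/exact
  logistic regression and automatic knot selection are deliberately out
  of scope.
* The HEI-2015 score and ETDRS grades are inputs, not computed here.
* Trained KDM parameters are portable via a flat text serialization, but
  clocks trained on the synthetic cohort are not transferable to real
  data — biomarker units must match the column dictionary exactly.
* Subgroup analyses on small strata inherit the small-cluster
  anti-conservatism discussed above; flagged rows mark degenerate cells
  but cannot rescue unstable fits.
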