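#' Synthetic NHANES-like cohort generator
#'
#' Generates cohorts with a stratified multistage design, a latent
#' biological-aging process, biomarkers that are noisy linear functions of
#' latent age, diabetes assigned by the glucose/HbA1c rules of the cohort
#' module, and diabetic retinopathy assigned among diabetic subjects by a
#' logistic model with a configurable per-year effect of latent age. Every
#' downstream stage of the pipeline can therefore be tested against known
#' ground truth.
#'
#' The latent model is `B = CA + delta`, `delta ~ N(0, latent_sd^2)`
#' independent of CA. Biomarkers are independent Gaussians around linear
#' functions of `B` (log-CRP simulated directly on the log scale). Weights
#' are drawn independently of the outcome (ignorable design) and scaled so
#' they sum to `pop_size`.
#'
#' @name synthetic
NULL

#' Default biomarker loadings
#'
#' Slope/intercept/noise-SD of each biomarker on latent biological age
#' (intercept given at latent age 60). Values are chosen to be physiologic
#' for a US adult examination cohort; they are generator conditions, not
#' fitted quantities.
#'
#' @return data.frame `(biomarker, intercept, slope, sd)`.
#' @export
defaultLoadings <- function() {
  data.frame(
    biomarker = c("ln_crp", "creatinine", "hba1c", "albumin",
                  "total_cholesterol", "urea_nitrogen", "alk_phos",
                  "fasting_glucose", "lymphocyte_pct", "mcv", "rdw", "wbc"),
    intercept = c(-1.75, 75, 5.45, 43.5, 5.2, 5.1, 70, 5.3, 31, 90, 12.9, 7.1),
    slope = c(0.018, 0.45, 0.012, -0.06, 0.012, 0.05, 0.35, 0.018,
              -0.10, 0.06, 0.016, 0.005),
    sd = c(0.95, 14, 0.40, 2.6, 1.0, 1.6, 19, 0.55, 7.5, 4.2, 0.85, 1.7),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param n_subjects cohort size.
#' @param n_strata number of design strata.
#' @param psus_per_stratum PSUs per stratum (>= 2).
#' @param weight_law list describing the positive weight distribution
#'   (`lognormal` with `sdlog`).
#' @param pop_size pseudo-population size; weights are scaled to sum to it.
#' @param ca_range chronological-age range (years), uniform.
#' @param latent_sd SD of the latent-aging deviation delta (years).
#' @param biomarker_loadings per-biomarker intercept/slope/noise table, as
#'   [defaultLoadings()]; intercepts are anchored at latent age
#'   `age_anchor`.
#' @param age_anchor latent age (years) at which intercepts/log-odds are
#'   anchored.
#' @param beta_latent log-odds of DR per year of latent biological age.
#' @param beta_ca_direct additional log-odds per year of CA given latent age.
#' @param covariate_effects named list of per-covariate log-odds on DR
#'   (defaults: all zero, so the designed exposure OR is the crude-model
#'   estimand).
#' @param dr_intercept DR log-odds among DM at the anchor age. The default
#'   (-2.163) is solved once so that, under the default conditions, the
#'   population DR prevalence among DM is 27.1% (the anchor age sits below
#'   the mean latent age of the DM subpopulation, which is why the value is
#'   below `qlogis(0.271)`).
#' @param dm_intercept,dm_slope log-odds of the dysglycemia liability at and
#'   per year away from the anchor age.
#' @param dm_thresholds glucose/HbA1c cutoffs re-used from the cohort rules
#'   (informational; classification always goes through [classifyDM()]).
#' @param weight_outcome_factor multiplies the weights of DR cases
#'   (default 1 = ignorable design; other values stress-test design-based
#'   variance).
#' @return Object of class `sim_config`.
#' @export
simConfig <- function(n_subjects = 3100, n_strata = 15, psus_per_stratum = 2,
                      weight_law = list(dist = "lognormal", sdlog = 0.5),
                      pop_size = 20 * n_subjects,
                      ca_range = c(40, 85), latent_sd = 5,
                      biomarker_loadings = defaultLoadings(),
                      age_anchor = 60,
                      beta_latent = log(1.11), beta_ca_direct = 0,
                      covariate_effects = list(),
                      dr_intercept = -2.163,
                      dm_intercept = -1.55, dm_slope = 0.03,
                      dm_thresholds = c(hba1c = 6.5, fasting_glucose = 7.0,
                                        ogtt_glucose = 11.1),
                      weight_outcome_factor = 1) {
  cfg <- list(n_subjects = n_subjects, n_strata = n_strata,
              psus_per_stratum = psus_per_stratum, weight_law = weight_law,
              pop_size = pop_size, ca_range = ca_range, latent_sd = latent_sd,
              biomarker_loadings = biomarker_loadings,
              age_anchor = age_anchor, beta_latent = beta_latent,
              beta_ca_direct = beta_ca_direct,
              covariate_effects = covariate_effects,
              dr_intercept = dr_intercept, dm_intercept = dm_intercept,
              dm_slope = dm_slope, dm_thresholds = dm_thresholds,
              weight_outcome_factor = weight_outcome_factor)
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid simulation config: field '", field, "' ", why)
  chk(cfg$n_subjects >= 1, "n_subjects", "must be >= 1")
  chk(cfg$n_strata >= 1, "n_strata", "must be >= 1")
  chk(cfg$psus_per_stratum >= 2, "psus_per_stratum", "must be >= 2")
  chk(cfg$latent_sd >= 0, "latent_sd", "must be >= 0")
  chk(cfg$pop_size > 0, "pop_size", "must be positive")
  chk(length(cfg$ca_range) == 2 && diff(cfg$ca_range) > 0, "ca_range",
      "must be an increasing (min, max) pair")
  chk(all(cfg$biomarker_loadings$sd >= 0), "biomarker_loadings",
      "noise SDs must be >= 0")
  chk(is.numeric(cfg$weight_outcome_factor) && cfg$weight_outcome_factor > 0,
      "weight_outcome_factor", "must be positive")
  invisible(cfg)
}

#' Designed odds ratio per year of latent age
#'
#' @param config a `sim_config`.
#' @return `exp(beta_latent)`.
#' @export
designedOR <- function(config) exp(config$beta_latent)

# Per-stage substream seeding: stage k of a run with seed s re-seeds the RNG
# at s*101 + k, so adding a later stage never perturbs earlier draws.
.stage_seed <- function(seed, stage) {
  s <- seed * 101 + stage
  if (s >= .Machine$integer.max) s <- s %% .Machine$integer.max
  set.seed(as.integer(s))
}

#' Simulate a cohort with known ground truth
#'
#' @param config a `sim_config`.
#' @param seed integer seed; identical (config, seed) pairs give identical
#'   cohorts.
#' @return list with `cohort` (standard [cohortColumns()] table) and `truth`
#'   (per-subject `id`, `ca`, `delta`, `latent_age`, `dysglycemic`,
#'   `dr_linpred`), with designed ORs in `attr(truth, "designed")`.
#' @export
simulateCohort <- function(config, seed) {
  .validate_sim_config(config)
  cfg <- config
  n <- cfg$n_subjects
  a0 <- cfg$age_anchor

  # stage 1: design structure
  .stage_seed(seed, 1)
  stratum <- sample(rep_len(seq_len(cfg$n_strata), n))
  psu <- sample(rep_len(seq_len(cfg$psus_per_stratum), n))
  w_raw <- switch(cfg$weight_law$dist,
    lognormal = stats::rlnorm(n, 0, cfg$weight_law$sdlog),
    uniform = stats::runif(n, 0.5, 1.5),
    stop("unknown weight_law dist: ", cfg$weight_law$dist))

  # stage 2: demographics and lifestyle covariates
  .stage_seed(seed, 2)
  ca <- stats::runif(n, cfg$ca_range[1], cfg$ca_range[2])
  sex <- sample(c("female", "male"), n, TRUE)
  race <- sample(c("nh_white", "nh_black", "mexican_american",
                   "other_hispanic", "other"), n, TRUE,
                 prob = c(0.72, 0.11, 0.08, 0.05, 0.04))
  education <- sample(c("less_hs", "hs", "above_hs"), n, TRUE,
                      prob = c(0.21, 0.25, 0.54))
  marital <- sample(c("married", "never_married", "partner", "other"),
                    n, TRUE, prob = c(0.65, 0.08, 0.05, 0.22))
  pir <- pmin(stats::rgamma(n, shape = 2.2, scale = 1.6), 5)
  physical_activity <- stats::rlnorm(n, log(450), 0.9)
  hei2015 <- pmin(pmax(stats::rnorm(n, 55, 12), 0), 100)
  bmi <- pmin(pmax(stats::rnorm(n, 28.8, 5.5), 15), 60)
  smoking <- sample(c("never", "former", "now"), n, TRUE,
                    prob = c(0.48, 0.33, 0.19))
  drinking <- sample(c("never", "former", "mild", "moderate", "heavy"),
                     n, TRUE, prob = c(0.09, 0.19, 0.43, 0.16, 0.13))

  # stage 3: latent aging
  .stage_seed(seed, 3)
  delta <- stats::rnorm(n, 0, cfg$latent_sd)
  B <- ca + delta

  # stage 4: biomarkers as noisy linear functions of latent age
  .stage_seed(seed, 4)
  L <- cfg$biomarker_loadings
  bio <- lapply(seq_len(nrow(L)), function(j)
    L$intercept[j] + L$slope[j] * (B - a0) + stats::rnorm(n, 0, L$sd[j]))
  names(bio) <- L$biomarker
  # blood pressure: a person-level set point rising with latent age plus
  # per-reading measurement noise; the first reading runs slightly high
  sbp_set <- 126 + 0.9 * (B - a0) + stats::rnorm(n, 0, 17)
  dbp_set <- 73 + 0.02 * (B - a0) + stats::rnorm(n, 0, 11)
  sbp1 <- sbp_set + 2 + stats::rnorm(n, 0, 3)
  sbp2 <- sbp_set + stats::rnorm(n, 0, 3)
  sbp3 <- sbp_set + stats::rnorm(n, 0, 3)
  dbp1 <- dbp_set + 1 + stats::rnorm(n, 0, 2.5)
  dbp2 <- dbp_set + stats::rnorm(n, 0, 2.5)
  dbp3 <- dbp_set + stats::rnorm(n, 0, 2.5)
  cvd_history <- stats::runif(n) < stats::plogis(-2.8 + 0.05 * (B - a0))

  # stage 5: dysglycemia liability -> DM markers
  .stage_seed(seed, 5)
  p_dys <- stats::plogis(cfg$dm_intercept + cfg$dm_slope * (B - a0))
  dys <- stats::runif(n) < p_dys
  bio$fasting_glucose[dys] <- bio$fasting_glucose[dys] +
    stats::rnorm(sum(dys), 3.5, 1.0)
  bio$hba1c[dys] <- bio$hba1c[dys] + stats::rnorm(sum(dys), 1.6, 0.6)
  dm_doctor_dx <- dys & stats::runif(n) < 0.6
  dm_medication <- dys & stats::runif(n) < 0.5
  ogtt_glucose <- bio$fasting_glucose + 2.0 + stats::rnorm(n, 0, 1.2)
  fasting_insulin <- stats::rlnorm(n, log(9) + 0.6 * dys, 0.5)

  is_dm <- classifyDM(dm_doctor_dx, bio$hba1c, bio$fasting_glucose,
                      ogtt_glucose, dm_medication)

  # stage 6: DR among DM via the configured logistic model
  .stage_seed(seed, 6)
  eff <- cfg$covariate_effects
  covlp <- rep(0, n)
  add_eff <- function(lp, nm, value) {
    if (!is.null(eff[[nm]])) lp + eff[[nm]] * value else lp
  }
  covlp <- add_eff(covlp, "male", as.numeric(sex == "male"))
  covlp <- add_eff(covlp, "bmi", bmi - 28.8)
  covlp <- add_eff(covlp, "smoking_now", as.numeric(smoking == "now"))
  covlp <- add_eff(covlp, "cvd_history", as.numeric(cvd_history))
  lp <- cfg$dr_intercept + cfg$beta_latent * (B - a0) +
    cfg$beta_ca_direct * (ca - a0) + covlp
  dr <- is_dm & stats::runif(n) < stats::plogis(lp)

  # ETDRS eye grades consistent with DR status
  .stage_seed(seed, 7)
  worse <- ifelse(dr, sample(c(20, 31, 43), n, TRUE, prob = c(0.5, 0.3, 0.2)),
                  ifelse(stats::runif(n) < 0.03, 14, 10))
  other <- pmin(worse, ifelse(stats::runif(n) < 0.5, worse, 10))
  swap <- stats::runif(n) < 0.5
  etdrs_left <- ifelse(swap, worse, other)
  etdrs_right <- ifelse(swap, other, worse)

  weight <- w_raw * ifelse(dr, cfg$weight_outcome_factor, 1)
  weight <- weight * cfg$pop_size / sum(weight)

  cohort <- data.frame(
    id = seq_len(n), ca = ca, sex = sex, race_ethnicity = race,
    education = education, marital = marital, pir = pir,
    physical_activity = physical_activity, hei2015 = hei2015, bmi = bmi,
    smoking = smoking, drinking = drinking, cvd_history = cvd_history,
    sbp1 = sbp1, sbp2 = sbp2, sbp3 = sbp3,
    dbp1 = dbp1, dbp2 = dbp2, dbp3 = dbp3,
    dm_doctor_dx = dm_doctor_dx, hba1c = bio$hba1c,
    fasting_glucose = bio$fasting_glucose, ogtt_glucose = ogtt_glucose,
    dm_medication = dm_medication, fasting_insulin = fasting_insulin,
    etdrs_left = etdrs_left, etdrs_right = etdrs_right,
    albumin = bio$albumin, creatinine = bio$creatinine,
    ln_crp = bio$ln_crp, lymphocyte_pct = bio$lymphocyte_pct,
    mcv = bio$mcv, rdw = bio$rdw, alk_phos = bio$alk_phos, wbc = bio$wbc,
    total_cholesterol = bio$total_cholesterol,
    urea_nitrogen = bio$urea_nitrogen,
    stratum = stratum, psu = psu, weight = weight,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(id = seq_len(n), ca = ca, delta = delta,
                      latent_age = B, dysglycemic = dys, dr_linpred = lp)
  attr(truth, "designed") <- list(or_per_year_latent = exp(cfg$beta_latent),
                                  or_per_year_ca_direct = exp(cfg$beta_ca_direct),
                                  covariate_or = lapply(eff, exp))
  list(cohort = cohort, truth = truth)
}

#' Write a simulated cohort and its ground-truth sidecar
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fc <- file.path(dir, "cohort.tsv")
  ft <- file.path(dir, "truth.tsv")
  utils::write.table(sim$cohort, fc, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(sim$truth, ft, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(cohort = fc, truth = ft))
}
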