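#' Cohort derivation rules
#'
#' Functions mapping raw examination/questionnaire fields to the analysis
#' variables: diabetes mellitus (DM) and diabetic retinopathy (DR) status,
#' averaged blood pressure, hypertension, HOMA-IR, smoking and drinking
#' categories, BMI, and the sequential exclusion cascade that defines the
#' analytic sample.
#'
#' @name cohort
NULL

#' Standard cohort column dictionary
#'
#' The delimited cohort table uses one row per participant with these
#' columns. Units: ages in years, glucose in mmol/L, HbA1c in %, insulin in
#' uU/mL, albumin g/L, creatinine umol/L, alkaline phosphatase U/L, blood
#' pressure mmHg, CRP carried as `ln_crp` = ln(CRP in mg/dL).
#'
#' @return Named character vector mapping column name to a short description.
#' @export
cohortColumns <- function() {
  c(id = "subject identifier",
    ca = "chronological age (years)",
    sex = "female/male",
    race_ethnicity = "mexican_american/other_hispanic/nh_white/nh_black/other",
    education = "less_hs/hs/above_hs",
    marital = "married/never_married/partner/other",
    pir = "poverty income ratio",
    physical_activity = "minutes/week",
    hei2015 = "Healthy Eating Index 2015 (0-100)",
    bmi = "kg/m^2",
    smoking = "never/former/now",
    drinking = "never/former/mild/moderate/heavy",
    cvd_history = "TRUE/FALSE",
    sbp1 = "systolic reading 1 (mmHg)", sbp2 = "systolic reading 2",
    sbp3 = "systolic reading 3",
    dbp1 = "diastolic reading 1 (mmHg)", dbp2 = "diastolic reading 2",
    dbp3 = "diastolic reading 3",
    dm_doctor_dx = "doctor-diagnosed diabetes",
    hba1c = "glycohemoglobin (%)",
    fasting_glucose = "fasting plasma glucose (mmol/L)",
    ogtt_glucose = "random/2-h OGTT glucose (mmol/L)",
    dm_medication = "diabetes medication or insulin use",
    fasting_insulin = "fasting insulin (uU/mL)",
    etdrs_left = "ETDRS severity level, left eye",
    etdrs_right = "ETDRS severity level, right eye",
    albumin = "serum albumin (g/L)", creatinine = "serum creatinine (umol/L)",
    ln_crp = "ln C-reactive protein (mg/dL)",
    lymphocyte_pct = "lymphocyte percent (%)", mcv = "mean cell volume (fL)",
    rdw = "red cell distribution width (%)",
    alk_phos = "alkaline phosphatase (U/L)",
    wbc = "white blood cell count (1000 cells/uL)",
    total_cholesterol = "total cholesterol (mmol/L)",
    urea_nitrogen = "serum urea nitrogen (mmol/L)",
    stratum = "design stratum", psu = "primary sampling unit (within stratum)",
    weight = "sampling weight")
}

#' Classify diabetes mellitus
#'
#' DM is present when any criterion holds: doctor diagnosis, HbA1c strictly
#' exceeding 6.5%, fasting glucose of 7.0 mmol/L or higher, random/2-h OGTT
#' glucose reaching 11.1 mmol/L or above, or use of diabetes medication or
#' insulin. The boundary semantics follow the wording literally: the HbA1c
#' cutoff is strict ("exceeding"), the glucose cutoffs inclusive.
#' Missing markers do not veto a positive criterion; a record with every
#' marker missing yields `NA` (to be excluded upstream).
#'
#' @param doctor_dx logical, doctor-diagnosed diabetes.
#' @param hba1c glycohemoglobin, %.
#' @param fasting_glucose fasting plasma glucose, mmol/L.
#' @param ogtt_glucose random or 2-h OGTT glucose, mmol/L (either field;
#'   supply whichever is measured).
#' @param dm_medication logical, diabetes medication/insulin use.
#' @return Logical vector (NA when all markers missing).
#' @export
classifyDM <- function(doctor_dx = NA, hba1c = NA, fasting_glucose = NA,
                       ogtt_glucose = NA, dm_medication = NA) {
  n <- max(length(doctor_dx), length(hba1c), length(fasting_glucose),
           length(ogtt_glucose), length(dm_medication))
  crit <- cbind(rep_len(as.logical(doctor_dx), n),
                rep_len(hba1c, n) > 6.5,
                rep_len(fasting_glucose, n) >= 7.0,
                rep_len(ogtt_glucose, n) >= 11.1,
                rep_len(as.logical(dm_medication), n))
  any_true <- rowSums(crit, na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(crit)) == 0
  out <- any_true
  out[all_na] <- NA
  out
}

#' Classify diabetic retinopathy
#'
#' DR is identified only among DM participants: the person shows one or more
#' retinal microaneurysms or blot hemorrhages (with or without severer
#' lesions) on graded retinal images. Grades are per-eye ordinal ETDRS
#' severity levels; `lesion_level` is the lowest level counting as at least
#' one microaneurysm or blot hemorrhage (default 20, microaneurysms only).
#' If one eye is ungradable its grade is imputed from the other eye; the
#' person-level grade is the worse eye. Non-DM records are `FALSE`
#' regardless of grades; DM records with both eyes ungradable are `NA`.
#'
#' @param is_dm logical DM status from [classifyDM()].
#' @param grade_left,grade_right per-eye ETDRS levels (NA = ungradable).
#' @param lesion_level minimum level counting as retinopathy.
#' @return Logical vector.
#' @export
classifyDR <- function(is_dm, grade_left, grade_right, lesion_level = 20) {
  n <- max(length(is_dm), length(grade_left), length(grade_right))
  is_dm <- rep_len(is_dm, n)
  gl <- rep_len(grade_left, n); gr <- rep_len(grade_right, n)
  gl2 <- ifelse(is.na(gl), gr, gl)   # other-eye imputation
  gr2 <- ifelse(is.na(gr), gl, gr)
  person <- pmax(gl2, gr2)           # worse eye
  out <- !is.na(is_dm) & is_dm & !is.na(person) & person >= lesion_level
  out[is_dm & is.na(person)] <- NA   # DM but no gradable eye
  out[!is.na(is_dm) & !is_dm] <- FALSE
  out
}

#' Average blood pressure readings
#'
#' For a single reading, that reading is the average. For multiple readings
#' the first is excluded, and zero-diastolic readings are excluded from the
#' mean unless all (remaining) diastolic values are zero. The two rules are
#' applied in that order: drop the first reading, then drop zero-diastolic
#' readings from the remainder; if that empties the set, fall back to all
#' readings minus zero-diastolic ones, and finally to the post-first set
#' unchanged.
#'
#' @param sbp,dbp numeric vectors of paired readings (NA entries are dropped).
#' @return Named numeric vector `c(sbp =, dbp =)`.
#' @export
averageBP <- function(sbp, dbp) {
  keep <- !is.na(sbp) & !is.na(dbp)
  sbp <- sbp[keep]; dbp <- dbp[keep]
  if (length(sbp) == 0) stop("no blood pressure readings")
  if (length(sbp) == 1) return(c(sbp = sbp, dbp = dbp))
  s <- sbp[-1]; d <- dbp[-1]
  if (any(d > 0)) {
    s <- s[d > 0]; d <- d[d > 0]
  } else if (any(dbp > 0)) {
    s <- sbp[dbp > 0]; d <- dbp[dbp > 0]
  }
  c(sbp = mean(s), dbp = mean(d))
}

#' Classify hypertension
#'
#' Hypertension when average systolic is >= 140 mmHg or average diastolic is
#' >= 90 mmHg (both boundaries inclusive).
#'
#' @param sbp,dbp averaged blood pressure, mmHg.
#' @return Logical vector.
#' @export
classifyHypertension <- function(sbp, dbp) sbp >= 140 | dbp >= 90

#' HOMA-IR insulin-resistance index
#'
#' `fasting glucose (mmol/L) x fasting insulin (uU/mL) / 22.5`.
#'
#' @param fasting_glucose mmol/L.
#' @param fasting_insulin uU/mL.
#' @return Numeric index.
#' @export
homaIR <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose < 0, na.rm = TRUE) ||
      any(fasting_insulin < 0, na.rm = TRUE))
    stop("glucose and insulin must be non-negative")
  fasting_glucose * fasting_insulin / 22.5
}

#' Classify drinking status
#'
#' Five categories: never (< 12 drinks in lifetime); former (>= 12 lifetime,
#' none in the past year); otherwise by average drinks per day in the last
#' 12 months with sex-specific cutoffs — heavy >= 3 (female) / >= 4 (male),
#' mild <= 1 (female) / <= 2 (male), moderate in between.
#'
#' @param lifetime_drinks drinks ever consumed.
#' @param past_year_drinks drinks in the past 12 months.
#' @param per_day average drinks per day in the last 12 months.
#' @param sex "female" or "male".
#' @return Character vector in
#'   `c("never","former","mild","moderate","heavy")`.
#' @export
classifyDrinking <- function(lifetime_drinks, past_year_drinks, per_day, sex) {
  n <- max(length(lifetime_drinks), length(past_year_drinks),
           length(per_day), length(sex))
  lifetime_drinks <- rep_len(lifetime_drinks, n)
  past_year_drinks <- rep_len(past_year_drinks, n)
  per_day <- rep_len(per_day, n); sex <- rep_len(sex, n)
  heavy_cut <- ifelse(sex == "female", 3, 4)
  mild_cut <- ifelse(sex == "female", 1, 2)
  out <- ifelse(lifetime_drinks < 12, "never",
         ifelse(past_year_drinks == 0, "former",
         ifelse(per_day >= heavy_cut, "heavy",
         ifelse(per_day <= mild_cut, "mild", "moderate"))))
  out
}

#' Classify smoking status
#'
#' Never (< 100 cigarettes in life), former (>= 100 and quit), now (>= 100
#' and currently smoking).
#'
#' @param lifetime_cigs cigarettes ever smoked.
#' @param currently_smoking logical.
#' @return Character vector in `c("never","former","now")`.
#' @export
classifySmoking <- function(lifetime_cigs, currently_smoking) {
  ifelse(lifetime_cigs < 100, "never",
         ifelse(currently_smoking, "now", "former"))
}

#' Body mass index
#'
#' @param weight_kg body weight, kg.
#' @param height_m height, m (> 0).
#' @return kg/m^2.
#' @export
computeBMI <- function(weight_kg, height_m) {
  if (any(height_m <= 0, na.rm = TRUE)) stop("height must be positive")
  weight_kg / height_m^2
}

#' Apply a sequential exclusion cascade
#'
#' Filters the cohort through named steps in order; a record failing several
#' steps is removed (and counted) at the earliest step only, so the counts
#' are order-dependent by design and sum with the final sample size to the
#' input size.
#'
#' @param data cohort data.frame.
#' @param steps named list; each element is either a character vector of
#'   column names (a record is dropped when any is `NA`) or a function of the
#'   data returning a logical drop indicator.
#' @return list with `data` (the analytic sample) and `report`, a data.frame
#'   `(step, n_removed, n_remaining)`.
#' @export
applyExclusions <- function(data, steps) {
  if (is.null(names(steps)) || any(names(steps) == ""))
    stop("steps must be a named list")
  report <- data.frame(step = character(), n_removed = integer(),
                       n_remaining = integer(), stringsAsFactors = FALSE)
  for (nm in names(steps)) {
    st <- steps[[nm]]
    drop <- if (is.function(st)) st(data) else
      Reduce(`|`, lapply(st, function(col) is.na(data[[col]])))
    drop[is.na(drop)] <- TRUE
    report <- rbind(report, data.frame(step = nm, n_removed = sum(drop),
                                       n_remaining = sum(!drop),
                                       stringsAsFactors = FALSE))
    data <- data[!drop, , drop = FALSE]
  }
  list(data = data, report = report)
}

#' Default exclusion cascade for the standard cohort table
#'
#' Three steps applied in order: (1) unavailable retinal imaging (both eyes
#' ungradable) or any missing aging-clock biomarker; (2) missing demographics
#' (sex, race/ethnicity, education, PIR, marital status); (3) missing other
#' covariates (physical activity, HEI-2015, drinking, smoking, BMI, CVD
#' history, blood pressure).
#'
#' @return A named list of steps for [applyExclusions()].
#' @export
defaultExclusionSteps <- function() {
  clock_cols <- c("ln_crp", "creatinine", "hba1c", "albumin",
                  "total_cholesterol", "urea_nitrogen", "alk_phos",
                  "fasting_glucose", "lymphocyte_pct", "mcv", "rdw", "wbc")
  list(
    imaging_biomarkers = function(d) {
      no_eye <- is.na(d$etdrs_left) & is.na(d$etdrs_right)
      no_bm <- Reduce(`|`, lapply(clock_cols, function(cc) is.na(d[[cc]])))
      no_eye | no_bm | is.na(d$sbp1)
    },
    demographics = c("sex", "race_ethnicity", "education", "pir", "marital"),
    covariates = c("physical_activity", "hei2015", "drinking", "smoking",
                   "bmi", "cvd_history", "dbp1")
  )
}

#' Derive analysis variables on a raw cohort table
#'
#' Adds `sbp`/`dbp` (averaged readings), `hypertension`, `dm`, `dr`,
#' `homa_ir` columns using the rules above.
#'
#' @param data cohort data.frame using the [cohortColumns()] dictionary.
#' @return The augmented data.frame.
#' @export
deriveCohort <- function(data) {
  bp <- t(mapply(function(i) {
    averageBP(c(data$sbp1[i], data$sbp2[i], data$sbp3[i]),
              c(data$dbp1[i], data$dbp2[i], data$dbp3[i]))
  }, seq_len(nrow(data))))
  data$sbp <- bp[, "sbp"]
  data$dbp <- bp[, "dbp"]
  data$hypertension <- classifyHypertension(data$sbp, data$dbp)
  data$dm <- classifyDM(data$dm_doctor_dx, data$hba1c, data$fasting_glucose,
                        data$ogtt_glucose, data$dm_medication)
  data$dr <- classifyDR(data$dm, data$etdrs_left, data$etdrs_right)
  data$homa_ir <- homaIR(data$fasting_glucose, data$fasting_insulin)
  data
}
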