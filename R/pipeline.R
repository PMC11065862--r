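#' End-to-end analysis pipeline
#'
#' Runs the full study pipeline on a synthetic or file-based cohort:
#' exclusion cascade, aging-clock computation, weighted descriptives,
#' Model-1/2/3 odds-ratio ladder for each exposure, spline dose-response
#' curves, ROC/DCA evaluation, subgroup analyses and sensitivity analyses
#' (DM-restricted; additionally insulin/HOMA-IR adjusted), writing every
#' artifact as a delimited table plus a run manifest.
#'
#' @name pipeline
NULL

.kdm_panel <- c("ln_crp", "creatinine", "hba1c", "albumin",
                "total_cholesterol", "urea_nitrogen", "alk_phos", "sbp")

#' Pipeline run configuration
#'
#' @param input `"synthetic"` or a path to a delimited cohort table using
#'   the [cohortColumns()] dictionary.
#' @param sim_config a [simConfig()] used when `input = "synthetic"`.
#' @param exposures subset of `c("ba","pa","ca","ba_accel","pa_accel")`.
#' @param subgroups stratifying variables for subgroup analyses.
#' @param sensitivity_dm_only run the DM-restricted analysis?
#' @param sensitivity_insulin additionally adjust for fasting insulin and
#'   HOMA-IR in the DM-restricted analysis?
#' @param outdir output directory.
#' @param seed integer seed for the whole run.
#' @return Object of class `run_config`.
#' @export
runConfig <- function(input = "synthetic", sim_config = simConfig(),
                      exposures = c("ba", "pa", "ca", "ba_accel", "pa_accel"),
                      subgroups = c("ca_group", "sex", "race_ethnicity",
                                    "cvd_history", "hypertension",
                                    "smoking", "drinking"),
                      sensitivity_dm_only = TRUE, sensitivity_insulin = TRUE,
                      outdir = tempfile("bioagedr_run_"), seed = 1) {
  allowed <- c("ba", "pa", "ca", "ba_accel", "pa_accel")
  if (!all(exposures %in% allowed))
    stop("exposures must be a subset of: ", paste(allowed, collapse = ", "))
  if (!identical(input, "synthetic") && !file.exists(input))
    stop("cohort file not found: ", input)
  structure(list(input = input, sim_config = sim_config,
                 exposures = exposures, subgroups = subgroups,
                 sensitivity_dm_only = sensitivity_dm_only,
                 sensitivity_insulin = sensitivity_insulin,
                 outdir = outdir, seed = seed),
            class = "run_config")
}

.read_cohort <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

.require_columns <- function(data, cols, where) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing columns in ", where, ": ", paste(miss, collapse = ", "))
}

#' Prepare the analytic sample
#'
#' Derives the analysis variables, applies the exclusion cascade, trains the
#' KDM clock on the analytic sample, and attaches `ba`, `pa`, the
#' acceleration indicators and the age grouping used for trend/subgroup
#' analyses.
#'
#' @param cohort raw cohort data.frame.
#' @param kdm_params optional pre-trained clock; by default the clock is
#'   trained on the analytic sample.
#' @return list `(data, design, report, kdm_params)`.
#' @export
prepareAnalytic <- function(cohort, kdm_params = NULL) {
  .require_columns(cohort, c("ca", "stratum", "psu", "weight"), "cohort table")
  cohort <- deriveCohort(cohort)
  excl <- applyExclusions(cohort, defaultExclusionSteps())
  d <- excl$data
  if (is.null(kdm_params))
    kdm_params <- kdmTrain(d, .kdm_panel)
  sc <- kdmScore(d, kdm_params)
  d$ba <- sc$ba
  d$ba_accel <- sc$accelerated
  d$pa <- phenoageScore(d)
  d$pa_accel <- phenoageAcceleration(d$pa, d$ca)
  d$ca_group <- cut(d$ca, c(-Inf, 60, 70, Inf), right = FALSE,
                    labels = c("lt60", "60to69", "ge70"))
  d$ca_group <- factor(as.character(d$ca_group),
                       levels = c("lt60", "60to69", "ge70"))
  design <- surveyDesign(d$stratum, d$psu, d$weight)
  list(data = d, design = design, report = excl$report,
       kdm_params = kdm_params)
}

.table1 <- function(d, design) {
  cont <- c("ca", "pir", "physical_activity", "hei2015", "bmi", "ba", "pa")
  cat_vars <- c("ca_group", "sex", "race_ethnicity", "marital", "education",
                "smoking", "drinking", "cvd_history", "hypertension",
                "ba_accel", "pa_accel")
  rows <- list()
  for (v in cont) {
    ms <- svyMeanSE(d[[v]], design)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "", n = length(d[[v]]),
      stat = ms["mean"], se_or_pct = ms["se"], p = NA_real_,
      stringsAsFactors = FALSE)
  }
  for (v in cat_vars) {
    tab <- svyTable(d[[v]], design)
    p <- tryCatch(raoScottChi2(d[[v]], d$dr, design)$p, error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = tab$level, n = tab$n,
      stat = tab$pct, se_or_pct = NA_real_,
      p = c(p, rep(NA_real_, nrow(tab) - 1L)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.model_table <- function(d, design, exposures, outcome = "dr") {
  rows <- lapply(exposures, function(ex) {
    modelSuite(d, design, ex, outcome = outcome,
               adjust_age = !(ex %in% c("ca", "ca_group")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' @param config a [runConfig()].
#' @return Invisibly, a list with the in-memory results (`analytic`,
#'   `table1`, `models`, `trend`, `splines`, `evaluation`, `subgroups`,
#'   `sensitivity`, `manifest`) after writing each as a delimited file under
#'   `config$outdir`.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  cohort <- if (identical(config$input, "synthetic")) {
    simulateCohort(config$sim_config, config$seed)$cohort
  } else .read_cohort(config$input)
  .require_columns(cohort, setdiff(names(cohortColumns()), "id"), "cohort table")

  prep <- prepareAnalytic(cohort)
  d <- prep$data; design <- prep$design
  files <- character()

  files["exclusions"] <- .write_tsv(prep$report,
                                    file.path(config$outdir, "exclusion_flow.tsv"))
  kdmWrite(prep$kdm_params, file.path(config$outdir, "kdm_params.tsv"))
  files["kdm_params"] <- file.path(config$outdir, "kdm_params.tsv")

  t1 <- .table1(d, design)
  files["table1"] <- .write_tsv(t1, file.path(config$outdir, "table1.tsv"))

  models <- .model_table(d, design, config$exposures)
  files["models"] <- .write_tsv(models, file.path(config$outdir, "models.tsv"))

  trend <- data.frame(
    exposure = "ca_group",
    p_trend = trendTest(stats::as.formula(
      paste("dr ~ ca_group +", paste(c("sex", "race_ethnicity", "pir",
                                       "marital", "education",
                                       "physical_activity", "hei2015",
                                       "drinking", "smoking", "bmi",
                                       "cvd_history", "hypertension"),
                                     collapse = " + "))),
      d, design, "ca_group", levels = c("lt60", "60to69", "ge70")))
  files["trend"] <- .write_tsv(trend, file.path(config$outdir, "trend.tsv"))

  m3covs <- c("ca", "sex", "race_ethnicity", "pir", "marital", "education",
              "physical_activity", "hei2015", "drinking", "smoking", "bmi",
              "cvd_history", "hypertension")
  cont_exp <- intersect(config$exposures, c("ba", "pa", "ca"))
  splines <- lapply(cont_exp, function(ex) {
    covs <- setdiff(m3covs, if (ex == "ca") "ca" else character())
    sp <- fitSplineCurve(d, design, ex, covariates = covs)
    cbind(exposure = ex, sp$curve,
          p_nonlinear = c(sp$p_nonlinear, rep(NA, nrow(sp$curve) - 1L)))
  })
  splines <- do.call(rbind, splines)
  files["splines"] <- .write_tsv(splines, file.path(config$outdir, "splines.tsv"))

  ev <- comparePredictors(d, design, cont_exp,
                          covariates = setdiff(m3covs, "ca"))
  roc_tab <- do.call(rbind, lapply(names(ev), function(ex)
    cbind(exposure = ex, auc = ev[[ex]]$roc$auc, ev[[ex]]$roc$curve)))
  dca_tab <- do.call(rbind, lapply(names(ev), function(ex)
    cbind(exposure = ex, as.data.frame(ev[[ex]]$dca))))
  files["roc"] <- .write_tsv(roc_tab, file.path(config$outdir, "roc.tsv"))
  files["dca"] <- .write_tsv(dca_tab, file.path(config$outdir, "dca.tsv"))

  subgroups <- lapply(intersect(config$subgroups, names(d)), function(sv) {
    out <- lapply(intersect(config$exposures, c("ba", "pa", "ca")), function(ex) {
      sg <- subgroupAnalysis(d, design, ex, sv,
                             adjust_age = !(ex %in% c("ca")))
      cbind(exposure = ex, by = sv, sg,
            p_interaction = c(attr(sg, "p_interaction"),
                              rep(NA, nrow(sg) - 1L)))
    })
    do.call(rbind, out)
  })
  subgroups <- do.call(rbind, subgroups)
  files["subgroups"] <- .write_tsv(subgroups,
                                   file.path(config$outdir, "subgroups.tsv"))

  sens <- list()
  if (config$sensitivity_dm_only && sum(d$dm) > 0) {
    dd <- d[d$dm, , drop = FALSE]
    ddes <- surveyDesign(dd$stratum, dd$psu, dd$weight)
    sens$dm_only <- suppressWarnings(
      .model_table(dd, ddes, intersect(config$exposures, c("ba", "pa", "ca"))))
    if (config$sensitivity_insulin) {
      m3 <- function(ex) {
        covs <- c(setdiff(m3covs, if (ex == "ca") "ca" else character()),
                  "fasting_insulin", "homa_ir")
        fit <- suppressWarnings(svyLogit(stats::as.formula(
          paste("dr ~", paste(c(ex, covs), collapse = " + "))), dd, ddes))
        ci <- orCI(fit, grep(paste0("^", ex), fit$table$term, value = TRUE)[1])
        data.frame(model = "model3_insulin", exposure = ex, term = ex,
                   or = ci["or"], lo = ci["lo"], hi = ci["hi"], p = ci["p"],
                   stringsAsFactors = FALSE)
      }
      sens$insulin <- do.call(rbind, lapply(
        intersect(config$exposures, c("ba", "pa", "ca")), m3))
    }
    sens_tab <- do.call(rbind, Map(function(nm, tb) cbind(analysis = nm, tb),
                                   names(sens), sens))
    rownames(sens_tab) <- NULL
    files["sensitivity"] <- .write_tsv(sens_tab,
                                       file.path(config$outdir, "sensitivity.tsv"))
  }

  cfg_path <- file.path(config$outdir, "config.txt")
  writeLines(utils::capture.output(utils::str(config)), cfg_path)
  manifest <- data.frame(
    file = basename(c(files, config = cfg_path)),
    md5 = unname(tools::md5sum(c(files, config = cfg_path))),
    stringsAsFactors = FALSE)
  manifest <- rbind(manifest,
                    data.frame(file = c(".seed", ".package_version"),
                               md5 = c(as.character(config$seed),
                                       as.character(utils::packageVersion("bioagedr"))),
                               stringsAsFactors = FALSE))
  files["manifest"] <- .write_tsv(manifest,
                                  file.path(config$outdir, "manifest.tsv"))

  invisible(list(analytic = d, design = design, report = prep$report,
                 kdm_params = prep$kdm_params, table1 = t1, models = models,
                 trend = trend, splines = splines, evaluation = ev,
                 subgroups = subgroups, sensitivity = sens,
                 manifest = manifest, files = files))
}
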