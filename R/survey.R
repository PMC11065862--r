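#' Complex-survey design object
#'
#' Captures the stratum / primary-sampling-unit (PSU) / weight structure used
#' for design-based (Taylor-linearized) variance estimation. PSU identifiers
#' are interpreted as nested within strata. Strata contributing a single PSU
#' ("lonely PSU") are handled by centering that PSU's score total at the
#' grand mean of all PSU totals, with a warning.
#'
#' @param stratum stratum identifiers (any atomic type).
#' @param psu PSU identifiers, nested within stratum.
#' @param weight positive, finite sampling weights.
#' @return Object of class `svy_design`.
#' @export
surveyDesign <- function(stratum, psu, weight) {
  n <- length(weight)
  if (length(stratum) != n || length(psu) != n)
    stop("stratum, psu and weight must have equal length")
  if (anyNA(weight) || any(!is.finite(weight)) || any(weight <= 0))
    stop("weights must be positive and finite")
  if (anyNA(stratum) || anyNA(psu)) stop("missing stratum or psu identifiers")
  stratum <- as.character(stratum)
  cluster <- paste(stratum, psu, sep = "\r")
  structure(list(stratum = stratum, cluster = cluster, weight = weight,
                 n = n, n_psu = length(unique(cluster)),
                 n_strata = length(unique(stratum))),
            class = "svy_design")
}

#' @export
print.svy_design <- function(x, ...) {
  cat("Survey design:", x$n, "records,", x$n_strata, "strata,",
      x$n_psu, "PSUs; design df =", x$n_psu - x$n_strata, "\n")
  invisible(x)
}

#' Design degrees of freedom
#'
#' The conventional finite-design degrees of freedom, number of PSUs minus
#' number of strata.
#'
#' @param design a `svy_design`.
#' @return Integer df.
#' @export
degfSurvey <- function(design) design$n_psu - design$n_strata

# Stratified between-PSU covariance of linearized score contributions.
# u: n x p matrix of per-record contributions. Returns p x p matrix.
# Lonely-PSU strata are centered at the grand mean of PSU totals (warning).
.psu_covariance <- function(u, design) {
  u <- as.matrix(u)
  tot <- rowsum(u, design$cluster, reorder = FALSE)
  str_of_psu <- design$stratum[!duplicated(design$cluster)]
  p <- ncol(u)
  G <- matrix(0, p, p)
  grand <- colMeans(tot)
  lonely <- FALSE
  for (h in unique(str_of_psu)) {
    z <- tot[str_of_psu == h, , drop = FALSE]
    nh <- nrow(z)
    if (nh == 1L) {
      lonely <- TRUE
      d <- z[1L, ] - grand
      G <- G + tcrossprod(d)
    } else {
      zc <- sweep(z, 2, colMeans(z))
      G <- G + nh / (nh - 1) * crossprod(zc)
    }
  }
  if (lonely)
    warning("stratum with a single PSU: centered at the grand PSU-total mean")
  G
}

#' Design-based weighted mean and standard error
#'
#' Horvitz-Thompson ratio mean `sum(w x) / sum(w)` with a Taylor-linearized
#' SE from the stratified between-PSU variance of the residual contributions
#' `w (x - mean) / sum(w)`.
#'
#' @param x numeric vector.
#' @param design a `svy_design` aligned with `x`.
#' @return Named numeric `c(mean =, se =)`.
#' @export
svyMeanSE <- function(x, design) {
  if (length(x) != design$n) stop("x and design are not aligned")
  W <- sum(design$weight)
  m <- sum(design$weight * x) / W
  u <- design$weight * (x - m) / W
  v <- .psu_covariance(matrix(u, ncol = 1), design)[1, 1]
  c(mean = m, se = sqrt(v))
}

#' Weighted category table
#'
#' Per-level survey-weighted percentage and unweighted count.
#'
#' @param x factor or character vector.
#' @param design a `svy_design`.
#' @return data.frame `(level, n, pct)`; `pct` sums to 100.
#' @export
svyTable <- function(x, design) {
  x <- as.factor(x)
  w <- rowsum(design$weight, x)
  data.frame(level = levels(x), n = as.integer(table(x)),
             pct = 100 * as.vector(w) / sum(design$weight),
             stringsAsFactors = FALSE)
}

#' Rao-Scott second-order corrected chi-squared test
#'
#' Pearson's test of independence on the survey-weighted contingency table
#' of two categorical variables, with Rao and Scott's second-order
#' (Satterthwaite) correction for the design: the Pearson statistic,
#' computed from the weighted cell proportions and scaled by the sample
#' size, is referred to a scaled chi-squared distribution whose scale and
#' degrees of freedom match the first two moments of its design-based
#' asymptotic distribution (a weighted sum of chi-squared(1) variables with
#' weights the generalized design effects).
#'
#' @param x,y categorical vectors.
#' @param design a `svy_design`.
#' @return list with `statistic` (uncorrected design-weighted Pearson X^2),
#'   `adj_statistic`, `df` (Satterthwaite), `p`.
#' @export
raoScottChi2 <- function(x, y, design) {
  x <- droplevels(as.factor(x)); y <- droplevels(as.factor(y))
  r <- nlevels(x); cc <- nlevels(y)
  if (r < 2 || cc < 2)
    stop("contingency table collapsed: need >= 2 levels per margin")
  if (any(table(x) == 0) || any(table(y) == 0))
    stop("empty row or column in contingency table")
  n <- design$n
  W <- sum(design$weight)
  # weighted cell proportions, cells in column-major (x fastest) order
  cell <- interaction(x, y, lex.order = FALSE)
  idx <- matrix(seq_len(r * cc), nrow = r)
  phat <- as.vector(rowsum(design$weight, cell)[levels(cell), 1]) / W
  P <- matrix(phat, nrow = r)
  prow <- rowSums(P); pcol <- colSums(P)
  M <- outer(prow, pcol)
  X2 <- n * sum((P - M)^2 / M)

  # design covariance of the cell-proportion vector (ratio linearization)
  ind <- outer(as.integer(cell), seq_len(r * cc), `==`) + 0
  u <- design$weight * sweep(ind, 2, phat) / W
  V <- .psu_covariance(u, design)
  # multinomial covariance under the fitted independence proportions
  m <- as.vector(M)
  V0 <- (diag(m) - tcrossprod(m)) / n

  # Jacobian of the (r-1)(c-1) interaction residuals u_ij = p_ij - p_i. p_.j
  nr <- (r - 1) * (cc - 1)
  J <- matrix(0, nr, r * cc)
  row_of <- rep(seq_len(r), cc); col_of <- rep(seq_len(cc), each = r)
  k <- 0
  for (j in seq_len(cc - 1)) for (i in seq_len(r - 1)) {
    k <- k + 1
    J[k, ] <- (row_of == i & col_of == j) -
      (row_of == i) * pcol[j] - (col_of == j) * prow[i]
  }
  A <- J %*% V0 %*% t(J)
  B <- J %*% V %*% t(J)
  d <- Re(eigen(solve(A, B), only.values = TRUE)$values)
  d <- pmax(d, 0)
  scale <- sum(d^2) / sum(d)
  df <- sum(d)^2 / sum(d^2)
  list(statistic = X2, adj_statistic = X2 / scale, df = df,
       p = stats::pchisq(X2 / scale, df, lower.tail = FALSE))
}

#' Survey-weighted logistic regression
#'
#' Fits a logistic model by weighted maximum pseudo-likelihood
#' (Newton/IRLS), with a design-based sandwich covariance: the bread is the
#' weighted information, the meat the stratified between-PSU covariance of
#' the weighted score contributions (Taylor linearization). Inference uses a
#' t reference with design degrees of freedom (#PSUs - #strata).
#'
#' @param formula model formula; the response must be 0/1 or logical.
#' @param data data.frame holding the model variables.
#' @param design a `svy_design` aligned with `data` rows.
#' @param maxit,tol Newton iteration controls.
#' @return Object of class `svy_logit` with elements `coef`, `vcov`, `se`,
#'   `df`, `n`, `converged`, `formula`, and a tidy `table` of per-term
#'   OR / 95% CI / p.
#' @export
svyLogit <- function(formula, data, design, maxit = 50, tol = 1e-10) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (length(unique(y)) < 2) stop("outcome has a single class")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (nrow(X) != design$n) stop("data and design are not aligned")
  if (qr(X)$rank < ncol(X)) stop("model matrix is rank deficient (collinearity)")
  w <- design$weight
  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(min(max(sum(w * y) / sum(w), 1e-6), 1 - 1e-6))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    v <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X, X * (w * v))
    score <- crossprod(X, w * (y - p))
    step <- solve(info, score)
    beta <- beta + drop(step)
    dev <- -2 * sum(w * (y * stats::plogis(drop(X %*% beta), log.p = TRUE) +
                         (1 - y) * stats::plogis(-drop(X %*% beta), log.p = TRUE)))
    if (abs(dev - dev_old) < tol * (abs(dev) + 1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  if (!converged || max(abs(beta)) > 30)
    stop("survey logistic fit failed (non-convergence or separation); ",
         "max|beta| = ", format(max(abs(beta))))
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  if (max(abs(y - p)) < 1e-6)
    stop("survey logistic fit failed (perfect separation): ",
         "fitted probabilities reproduce the outcome exactly")
  info <- crossprod(X, X * (w * p * (1 - p)))
  bread <- solve(info)
  u <- X * (w * (y - p))
  G <- .psu_covariance(u, design)
  V <- bread %*% G %*% bread
  V <- (V + t(V)) / 2
  se <- sqrt(diag(V))
  df <- degfSurvey(design)
  tstat <- beta / se
  tab <- data.frame(term = colnames(X), beta = beta, se = se,
                    or = exp(beta),
                    lo = exp(beta - stats::qt(0.975, df) * se),
                    hi = exp(beta + stats::qt(0.975, df) * se),
                    p = 2 * stats::pt(-abs(tstat), df),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(coef = stats::setNames(beta, colnames(X)), vcov = V, se = se,
                 df = df, n = design$n, converged = converged,
                 formula = formula, table = tab, fitted = p,
                 deviance = dev),
            class = "svy_logit")
}

#' @export
print.svy_logit <- function(x, ...) {
  cat("Survey-weighted logistic regression (design df =", x$df, ")\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.svy_logit <- function(object, ...) object$coef

#' @export
vcov.svy_logit <- function(object, ...) object$vcov

#' Odds ratio with design-based confidence interval
#'
#' @param fit a `svy_logit`.
#' @param term coefficient name (as in `fit$table$term`).
#' @param level confidence level.
#' @return Named numeric `c(or, lo, hi, p)`.
#' @export
orCI <- function(fit, term, level = 0.95) {
  i <- match(term, fit$table$term)
  if (is.na(i)) stop("unknown term: ", term)
  b <- fit$table$beta[i]; se <- fit$table$se[i]
  q <- stats::qt(1 - (1 - level) / 2, fit$df)
  c(or = exp(b), lo = exp(b - q * se), hi = exp(b + q * se),
    p = fit$table$p[i])
}

#' Wald test of a set of coefficients
#'
#' Joint Wald test that the named coefficients are zero, referred to an F
#' distribution with (q, design df) degrees of freedom.
#'
#' @param fit a `svy_logit`.
#' @param terms coefficient names.
#' @return list `(statistic, df1, df2, p)`.
#' @export
waldTest <- function(fit, terms) {
  i <- match(terms, names(fit$coef))
  if (anyNA(i)) stop("unknown terms: ", paste(terms[is.na(i)], collapse = ", "))
  b <- fit$coef[i]
  V <- fit$vcov[i, i, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  q <- length(i)
  list(statistic = W / q, df1 = q, df2 = fit$df,
       p = stats::pf(W / q, q, fit$df, lower.tail = FALSE))
}

#' Linear trend test for an ordered categorical exposure
#'
#' Refits the model with the ordinal variable replaced by its level codes
#' 0, 1, 2, ... as a single continuous term and returns that term's Wald p.
#'
#' @param formula model formula containing `ordinal_term`.
#' @param data data.frame; `data[[ordinal_term]]` must be an ordered factor
#'   (or `levels` must be given).
#' @param design a `svy_design`.
#' @param ordinal_term name of the ordinal variable.
#' @param levels optional explicit level order.
#' @return p-value of the linear-trend coefficient.
#' @export
trendTest <- function(formula, data, design, ordinal_term, levels = NULL) {
  v <- data[[ordinal_term]]
  if (is.null(levels)) {
    if (!is.ordered(v)) stop("'", ordinal_term, "' must be an ordered factor ",
                             "(or supply 'levels')")
    levels <- base::levels(v)
  }
  code <- as.numeric(factor(as.character(v), levels = levels)) - 1
  if (anyNA(code)) stop("values outside declared levels")
  data[[ordinal_term]] <- code
  fit <- svyLogit(formula, data, design)
  unname(fit$table$p[fit$table$term == ordinal_term])
}

#' Interaction (effect-modification) test
#'
#' Adds the cross-product of `a` and `b` to the model and jointly Wald-tests
#' the product terms.
#'
#' @param outcome outcome column name.
#' @param a exposure column name (continuous or binary).
#' @param b modifier column name (categorical or continuous).
#' @param covariates character vector of adjustment columns.
#' @param data,design data and aligned design.
#' @return p-value of the joint interaction test.
#' @export
interactionTest <- function(outcome, a, b, covariates, data, design) {
  if (is.character(data[[b]])) data[[b]] <- factor(data[[b]])
  if (!is.null(data[[b]]) && is.factor(data[[b]]) && nlevels(droplevels(data[[b]])) < 2)
    stop("modifier '", b, "' is constant")
  covs <- setdiff(covariates, c(a, b))
  rhs <- paste(c(a, b, covs, paste0(a, ":", b)), collapse = " + ")
  fit <- svyLogit(stats::as.formula(paste(outcome, "~", rhs)), data, design)
  main <- svyLogit(stats::as.formula(
    paste(outcome, "~", paste(c(a, b, covs), collapse = " + "))), data, design)
  inter <- setdiff(names(fit$coef), names(main$coef))
  if (!length(inter)) stop("no interaction terms produced (rank deficiency?)")
  waldTest(fit, inter)$p
}

#' Model-1/2/3 adjustment ladder for one exposure
#'
#' Fits the crude model (Model 1), the demographics-adjusted model (Model 2:
#' age, sex, race/ethnicity, PIR, marital status, education) and the fully
#' adjusted model (Model 3: additionally physical activity, HEI-2015,
#' drinking, smoking, BMI, CVD history, hypertension). When the exposure is
#' chronological age itself (or derived from it), age is omitted from the
#' covariates (`adjust_age = FALSE`).
#'
#' @param data derived cohort data.frame.
#' @param design aligned `svy_design`.
#' @param exposure exposure column name.
#' @param outcome outcome column name (binary).
#' @param adjust_age include `age_col` in Models 2-3?
#' @param age_col,demographics,lifestyle covariate column names.
#' @return data.frame with one row per model: `(model, exposure, or, lo, hi, p)`,
#'   with the underlying fits in `attr(, "fits")`.
#' @export
modelSuite <- function(data, design, exposure, outcome = "dr",
                       adjust_age = TRUE, age_col = "ca",
                       demographics = c("sex", "race_ethnicity", "pir",
                                        "marital", "education"),
                       lifestyle = c("physical_activity", "hei2015",
                                     "drinking", "smoking", "bmi",
                                     "cvd_history", "hypertension")) {
  demo <- c(if (adjust_age) age_col, demographics)
  if (exposure %in% c(demo, lifestyle))
    stop("exposure '", exposure, "' also appears among the adjustment covariates")
  specs <- list(model1 = character(), model2 = demo,
                model3 = c(demo, lifestyle))
  fits <- lapply(specs, function(covs) {
    rhs <- paste(c(exposure, covs), collapse = " + ")
    svyLogit(stats::as.formula(paste(outcome, "~", rhs)), data, design)
  })
  term <- vapply(fits, function(f) {
    tt <- grep(paste0("^", exposure), f$table$term, value = TRUE)
    tt[1]
  }, "")
  rows <- mapply(function(f, tm, nm) {
    ci <- orCI(f, tm)
    data.frame(model = nm, exposure = exposure, term = tm,
               or = ci["or"], lo = ci["lo"], hi = ci["hi"], p = ci["p"],
               stringsAsFactors = FALSE)
  }, fits, term, names(fits), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Subgroup analysis with interaction p
#'
#' Refits the fully adjusted (Model-3) exposure model within each level of a
#' stratifying variable, removing that variable (and age, when stratifying
#' on an age grouping) from the covariates, and tests effect modification by
#' adding a cross-product term to the pooled model. Subgroups in which the
#' fit is degenerate (single outcome class, separation) are returned as
#' flagged rows rather than errors.
#'
#' @inheritParams modelSuite
#' @param by stratifying column name.
#' @param age_group_col if `by` equals this, age is also dropped from the
#'   covariates.
#' @return data.frame `(subgroup, n, n_cases, or, lo, hi, p, note)` with
#'   `attr(, "p_interaction")`.
#' @export
subgroupAnalysis <- function(data, design, exposure, by, outcome = "dr",
                             adjust_age = TRUE, age_col = "ca",
                             age_group_col = "ca_group",
                             demographics = c("sex", "race_ethnicity", "pir",
                                              "marital", "education"),
                             lifestyle = c("physical_activity", "hei2015",
                                           "drinking", "smoking", "bmi",
                                           "cvd_history", "hypertension")) {
  covs <- c(if (adjust_age && by != age_group_col) age_col,
            setdiff(c(demographics, lifestyle), by))
  lev <- unique(as.character(data[[by]]))
  rows <- lapply(lev, function(lv) {
    keep <- as.character(data[[by]]) == lv
    sub <- data[keep, , drop = FALSE]
    subdes <- surveyDesign(design$stratum[keep], design$cluster[keep],
                           design$weight[keep])
    ncase <- sum(sub[[outcome]])
    base <- data.frame(subgroup = lv, n = nrow(sub), n_cases = ncase,
                       or = NA_real_, lo = NA_real_, hi = NA_real_,
                       p = NA_real_, note = "", stringsAsFactors = FALSE)
    if (ncase == 0 || ncase == nrow(sub)) {
      base$note <- "single outcome class"
      return(base)
    }
    usable <- covs[vapply(covs, function(cc) {
      v <- sub[[cc]]
      length(unique(v)) > 1
    }, TRUE)]
    res <- tryCatch({
      fit <- suppressWarnings(svyLogit(stats::as.formula(
        paste(outcome, "~", paste(c(exposure, usable), collapse = " + "))),
        sub, subdes))
      tm <- grep(paste0("^", exposure), fit$table$term, value = TRUE)[1]
      ci <- orCI(fit, tm)
      base$or <- ci["or"]; base$lo <- ci["lo"]; base$hi <- ci["hi"]
      base$p <- ci["p"]
      base
    }, error = function(e) { base$note <- conditionMessage(e); base })
    res
  })
  out <- do.call(rbind, rows)
  p_int <- tryCatch(
    suppressWarnings(
      interactionTest(outcome, exposure, by, c(if (adjust_age) age_col,
                                               demographics, lifestyle),
                      data, design)),
    error = function(e) NA_real_)
  attr(out, "p_interaction") <- p_int
  out
}
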