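#' ROC curve and C-statistic
#'
#' Computes the receiver operating characteristic curve over the observed
#' score thresholds and the area under it (the C-statistic). The AUC is
#' computed as the Mann-Whitney concordance probability — the proportion of
#' case/control pairs in which the case scores higher, ties counting 1/2 —
#' which equals the trapezoidal area under the empirical curve. The optional
#' weighted variant replaces pair counts by products of the pair's weights.
#'
#' @param scores numeric predictor values (higher = more case-like).
#' @param labels binary outcome (0/1 or logical).
#' @param weights optional positive weights.
#' @return Object of class `roc_result`: list with `curve` (data.frame
#'   `threshold, fpr, tpr`) and `auc`.
#' @export
rocAuc <- function(scores, labels, weights = NULL) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (length(unique(labels)) < 2) stop("both outcome classes must be present")
  if (is.null(weights)) weights <- rep(1, length(scores))
  if (anyNA(scores) || anyNA(weights)) stop("missing scores or weights")

  W1 <- sum(weights[labels == 1]); W0 <- sum(weights[labels == 0])
  o <- order(scores)                 # ascending
  s <- scores[o]; y <- labels[o]; w <- weights[o]
  grp <- cumsum(c(TRUE, diff(s) > 0))
  w1g <- rowsum(w * y, grp)[, 1]
  w0g <- rowsum(w * (1 - y), grp)[, 1]
  below0 <- c(0, cumsum(w0g))[seq_along(w0g)]
  auc <- sum(w1g * (below0 + 0.5 * w0g)) / (W1 * W0)

  thr <- rev(s[!duplicated(grp)])    # descending unique scores
  tpr <- cumsum(rev(w1g)) / W1
  fpr <- cumsum(rev(w0g)) / W0
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC (C-statistic) =", format(x$auc, digits = 4),
      "over", nrow(x$curve) - 1, "thresholds\n")
  invisible(x)
}

#' Decision curve analysis
#'
#' Net benefit of classifying by `pred_prob >= p_t` at each threshold
#' probability `p_t`: `NB(p_t) = TP/n - FP/n * p_t/(1-p_t)`, together with
#' the treat-all and treat-none reference policies. The optional weighted
#' variant replaces counts by weight sums.
#'
#' @param pred_prob predicted probabilities in `[0, 1]`.
#' @param labels binary outcome.
#' @param thresholds threshold probabilities, all strictly inside (0, 1).
#' @param weights optional positive weights.
#' @return Object of class `dca_result`: data.frame `threshold, nb_model,
#'   nb_all, nb_none` with the prevalence in `attr(, "prevalence")`.
#' @export
decisionCurve <- function(pred_prob, labels,
                          thresholds = seq(0.01, 0.99, by = 0.01),
                          weights = NULL) {
  labels <- as.numeric(labels)
  if (any(pred_prob < 0 | pred_prob > 1)) stop("pred_prob must lie in [0, 1]")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  if (is.null(weights)) weights <- rep(1, length(labels))
  n <- sum(weights)
  prev <- sum(weights * labels) / n
  nb <- vapply(thresholds, function(pt) {
    pos <- pred_prob >= pt
    tp <- sum(weights * (pos & labels == 1)) / n
    fp <- sum(weights * (pos & labels == 0)) / n
    tp - fp * pt / (1 - pt)
  }, 0)
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- data.frame(threshold = thresholds, nb_model = nb, nb_all = nb_all,
                    nb_none = 0)
  attr(out, "prevalence") <- prev
  class(out) <- c("dca_result", "data.frame")
  out
}

#' Compare exposures as DR predictors
#'
#' For each exposure, fits the covariate-adjusted survey-logistic model and
#' evaluates its predicted probabilities with ROC/AUC and decision-curve
#' analysis on the analytic sample. `mode = "raw"` scores the raw exposure
#' values instead of model probabilities (ROC only; DCA needs
#' probabilities, so raw mode still uses the model for DCA).
#'
#' @param data derived cohort data.frame.
#' @param design aligned `svy_design`.
#' @param exposures character vector of exposure column names.
#' @param covariates adjustment columns for the per-exposure model.
#' @param outcome binary outcome column.
#' @param mode `"model"` (predicted probabilities) or `"raw"` (raw exposure
#'   as ROC score).
#' @param weighted use survey weights inside ROC/DCA?
#' @return Named list per exposure with elements `roc`, `dca`, `fit`.
#' @export
comparePredictors <- function(data, design, exposures,
                              covariates = character(), outcome = "dr",
                              mode = c("model", "raw"), weighted = FALSE) {
  mode <- match.arg(mode)
  w <- if (weighted) design$weight else NULL
  out <- lapply(exposures, function(ex) {
    rhs <- paste(c(ex, setdiff(covariates, ex)), collapse = " + ")
    fit <- svyLogit(stats::as.formula(paste(outcome, "~", rhs)), data, design)
    score <- if (mode == "raw") data[[ex]] else fit$fitted
    list(roc = rocAuc(score, data[[outcome]], w),
         dca = decisionCurve(fit$fitted, data[[outcome]], weights = w),
         fit = fit)
  })
  stats::setNames(out, exposures)
}
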