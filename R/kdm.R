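#' Klemera-Doubal biological age
#'
#' The Klemera-Doubal method (KDM) combines a panel of biomarkers into a
#' biological-age estimate. Each biomarker is regressed on chronological age
#' (CA) in a training sample; the per-biomarker slope `k`, intercept `q`,
#' root-mean-squared error `s` and variance explained `r2` then enter a
#' precision-weighted average. The biomarker-only estimate is
#' \deqn{BA_E = \sum_j (x_j - q_j) (k_j / s_j^2) \; / \; \sum_j (k_j/s_j)^2,}
#' and the final estimate shrinks `BA_E` toward CA with weight `1/S_BA^2`:
#' \deqn{BA = \left[\sum_j (x_j - q_j)(k_j/s_j^2) + CA/S_{BA}^2\right] /
#'            \left[\sum_j (k_j/s_j)^2 + 1/S_{BA}^2\right].}
#' `S_BA^2` is estimated from the training sample via the characteristic
#' correlation coefficient `r_char`.
#'
#' @name kdm
NULL

.kdm_s_floor_rel <- 1e-8   # s_j floor, relative to the biomarker SD
.kdm_sba2_floor <- 1e-6    # years^2

#' Fit per-biomarker regressions on chronological age
#'
#' Step 1 of the KDM: ordinary (optionally weighted) least-squares regression
#' of each biomarker on CA. `s` is the root mean squared residual (divisor
#' `n`) and `r2` the squared (weighted) correlation with CA.
#'
#' @param data training data.frame.
#' @param biomarkers character vector of biomarker column names.
#' @param ca_col name of the chronological-age column.
#' @param weights optional positive observation weights (e.g. survey weights).
#' @return data.frame with one row per biomarker: `biomarker`, `k`, `q`, `s`, `r2`.
#' @export
kdmFitRegressions <- function(data, biomarkers, ca_col = "ca", weights = NULL) {
  ca <- data[[ca_col]]
  if (length(unique(ca)) < 3) stop("need at least 3 distinct CA values")
  if (is.null(weights)) weights <- rep(1, length(ca))
  out <- lapply(biomarkers, function(bm) {
    x <- data[[bm]]
    if (is.null(x)) stop("biomarker column not found: ", bm)
    if (anyNA(x) || anyNA(ca)) stop("missing values in training data for ", bm)
    if (stats::sd(x) == 0) stop("degenerate fit: biomarker is constant: ", bm)
    fit <- stats::lm(x ~ ca, weights = weights)
    k <- unname(stats::coef(fit)[2L])
    q <- unname(stats::coef(fit)[1L])
    if (k == 0) stop("degenerate fit: zero slope for ", bm)
    res <- stats::residuals(fit)
    s <- sqrt(sum(weights * res^2) / sum(weights))
    if (s < .kdm_s_floor_rel * stats::sd(x))
      stop("degenerate fit: residual error below floor for ", bm)
    r2 <- stats::cov.wt(cbind(x, ca), wt = weights, cor = TRUE)$cor[1L, 2L]^2
    data.frame(biomarker = bm, k = k, q = q, s = s, r2 = r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Characteristic correlation coefficient
#'
#' Summarizes the biomarker-age correlations as
#' \deqn{r_{char} = \frac{\sum_j r_j^2/\sqrt{1-r_j^2}}{\sum_j r_j/\sqrt{1-r_j^2}}}
#' with \eqn{r_j = +\sqrt{r_j^2}}.
#'
#' @param r2 vector of per-biomarker variance-explained values in `[0, 1)`.
#' @return `r_char`, unitless.
#' @export
kdmRChar <- function(r2) {
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 values must lie in [0, 1)")
  r <- sqrt(r2)
  sum(r^2 / sqrt(1 - r^2)) / sum(r / sqrt(1 - r^2))
}

#' KDM scaling factor
#'
#' Estimates `S_BA^2`, the variance scale that governs how strongly CA pulls
#' the final estimate: the population variance (divisor `n`) of the
#' per-subject deviations `BA_E - CA` about their mean, minus the correction
#' `((1 - r_char^2)/r_char^2) * (CA_max - CA_min)^2 / (12 m)`. A non-positive
#' result is floored at a small positive value with a warning.
#'
#' @param ba_e vector of biomarker-only estimates from [kdmBAE()].
#' @param ca matching chronological ages.
#' @param r_char characteristic correlation from [kdmRChar()].
#' @param ca_min,ca_max training CA range in years.
#' @param m number of biomarkers.
#' @return `S_BA^2` in years^2.
#' @export
kdmSBA2 <- function(ba_e, ca, r_char, ca_min, ca_max, m) {
  if (length(ba_e) != length(ca) || length(ba_e) < 2)
    stop("ba_e and ca must have equal length >= 2")
  if (r_char == 0) stop("degenerate r_char = 0")
  d <- ba_e - ca
  v <- mean((d - mean(d))^2)
  s2 <- v - ((1 - r_char^2) / r_char^2) * (ca_max - ca_min)^2 / (12 * m)
  if (s2 <= 0) {
    warning("S_BA^2 non-positive (", format(s2), "); floored at ", .kdm_sba2_floor)
    s2 <- .kdm_sba2_floor
  }
  s2
}

#' Train a KDM clock
#'
#' Runs the full training sequence on a cohort: per-biomarker regressions,
#' `r_char`, `BA_E` on the training sample, and `S_BA^2`.
#'
#' @inheritParams kdmFitRegressions
#' @return An object of class `kdm_params`: a list with elements
#'   `markers` (the regression table), `r_char`, `s_ba2`, `ca_min`, `ca_max`,
#'   `m`, `n`.
#' @export
kdmTrain <- function(data, biomarkers, ca_col = "ca", weights = NULL) {
  markers <- kdmFitRegressions(data, biomarkers, ca_col, weights)
  ca <- data[[ca_col]]
  p <- structure(list(markers = markers, r_char = kdmRChar(markers$r2),
                      s_ba2 = NA_real_, ca_min = min(ca), ca_max = max(ca),
                      m = nrow(markers), n = nrow(data)),
                 class = "kdm_params")
  ba_e <- kdmBAE(data[biomarkers], p)
  p$s_ba2 <- kdmSBA2(ba_e, ca, p$r_char, p$ca_min, p$ca_max, p$m)
  p
}

#' @export
print.kdm_params <- function(x, ...) {
  cat("Klemera-Doubal clock:", x$m, "biomarkers, trained on n =", x$n, "\n")
  cat("  CA range:", format(x$ca_min), "-", format(x$ca_max), "years\n")
  cat("  r_char =", format(x$r_char, digits = 4),
      " S_BA^2 =", format(x$s_ba2, digits = 4), "years^2\n")
  print(x$markers, row.names = FALSE)
  invisible(x)
}

.kdm_marker_matrix <- function(x, params) {
  bm <- params$markers$biomarker
  if (is.data.frame(x)) {
    miss <- setdiff(bm, names(x))
    if (length(miss)) stop("missing biomarkers: ", paste(miss, collapse = ", "))
    x <- as.matrix(x[bm])
  } else {
    x <- matrix(x, ncol = params$m)
  }
  if (anyNA(x)) stop("missing biomarker values; KDM requires all markers present")
  x
}

#' Biomarker-only biological age estimate
#'
#' @param x a data.frame with the training biomarker columns, or a numeric
#'   vector/matrix in training-biomarker order.
#' @param params a `kdm_params` object.
#' @return `BA_E` in years, one value per row.
#' @export
kdmBAE <- function(x, params) {
  x <- .kdm_marker_matrix(x, params)
  k <- params$markers$k; q <- params$markers$q; s <- params$markers$s
  num <- sweep(x, 2, q) %*% (k / s^2)
  drop(num) / sum((k / s)^2)
}

#' Final KDM biological age
#'
#' Shrinks `BA_E` toward chronological age with weight `1/S_BA^2`; the result
#' is a convex combination of `BA_E` and `CA`. `accelerated` flags `BA > CA`.
#'
#' @inheritParams kdmBAE
#' @param ca chronological age in years, one per row of `x`.
#' @return data.frame with columns `ba_e`, `ba`, `accelerated`.
#' @export
kdmBA <- function(x, ca, params) {
  if (is.na(params$s_ba2) || params$s_ba2 <= 0)
    stop("degenerate S_BA^2; train the clock first")
  x <- .kdm_marker_matrix(x, params)
  k <- params$markers$k; q <- params$markers$q; s <- params$markers$s
  num <- drop(sweep(x, 2, q) %*% (k / s^2))
  den <- sum((k / s)^2)
  ba_e <- num / den
  ba <- (num + ca / params$s_ba2) / (den + 1 / params$s_ba2)
  data.frame(ba_e = ba_e, ba = ba, accelerated = ba > ca)
}

#' Score a cohort with a trained KDM clock
#'
#' @param data cohort data.frame containing the training biomarker columns
#'   and `ca_col`.
#' @param params a `kdm_params` object.
#' @param ca_col chronological-age column name.
#' @return data.frame with `ba_e`, `ba`, `accelerated` (one row per subject).
#' @export
kdmScore <- function(data, params, ca_col = "ca") {
  kdmBA(data[params$markers$biomarker], data[[ca_col]], params)
}

#' Write / read KDM parameters as a flat text file
#'
#' Serializes a trained clock to a diffable key-value table (tab-separated)
#' so clocks are portable across runs.
#'
#' @param params a `kdm_params` object.
#' @param path file path.
#' @return `kdmWrite` returns `path` invisibly; `kdmRead` returns the
#'   reconstructed `kdm_params` object.
#' @export
kdmWrite <- function(params, path) {
  hdr <- c(r_char = params$r_char, s_ba2 = params$s_ba2,
           ca_min = params$ca_min, ca_max = params$ca_max,
           m = params$m, n = params$n)
  lines <- c(
    sprintf("%s\t%s", names(hdr), formatC(hdr, format = "g", digits = 17)),
    sprintf("marker\t%s\t%s\t%s\t%s\t%s", params$markers$biomarker,
            formatC(params$markers$k, format = "g", digits = 17),
            formatC(params$markers$q, format = "g", digits = 17),
            formatC(params$markers$s, format = "g", digits = 17),
            formatC(params$markers$r2, format = "g", digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname kdmWrite
#' @export
kdmRead <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  kv <- lines[lengths(lines) == 2L]
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                         vapply(kv, `[`, "", 1L))
  mk <- lines[vapply(lines, `[`, "", 1L) == "marker"]
  markers <- data.frame(
    biomarker = vapply(mk, `[`, "", 2L),
    k = as.numeric(vapply(mk, `[`, "", 3L)),
    q = as.numeric(vapply(mk, `[`, "", 4L)),
    s = as.numeric(vapply(mk, `[`, "", 5L)),
    r2 = as.numeric(vapply(mk, `[`, "", 6L)),
    stringsAsFactors = FALSE
  )
  structure(list(markers = markers, r_char = hdr[["r_char"]],
                 s_ba2 = hdr[["s_ba2"]], ca_min = hdr[["ca_min"]],
                 ca_max = hdr[["ca_max"]], m = as.integer(hdr[["m"]]),
                 n = as.integer(hdr[["n"]])),
            class = "kdm_params")
}
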