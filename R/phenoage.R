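#' Phenotypic Age coefficient table
#'
#' The fixed coefficients of the Phenotypic Age linear predictor `xb` and the
#' outer Gompertz-derived constants. Phenotypic Age maps nine blood biomarkers
#' plus chronological age onto the age scale through a mortality-hazard model;
#' the coefficients are published constants and are not re-estimated here.
#'
#' @return A data.frame with columns `term`, `coefficient`, `unit`.
#' @export
phenoageCoefficients <- function() {
  data.frame(
    term = c("intercept", "albumin", "creatinine", "glucose", "ln_crp",
             "lymphocyte_pct", "mcv", "rdw", "alk_phos", "wbc", "ca"),
    coefficient = c(-19.907, -0.0336, 0.0095, 0.1953, 0.0954,
                    -0.0120, 0.0268, 0.3306, 0.00188, 0.0554, 0.0804),
    unit = c("", "g/L", "umol/L", "mmol/L", "ln(mg/dL)",
             "%", "fL", "%", "U/L", "1000 cells/uL", "years"),
    stringsAsFactors = FALSE
  )
}

# outer constants of the Phenotypic Age transform
.pa_const <- list(a = 141.50, b = 0.09165, g1 = 0.00553, g2 = 1.51714, g3 = 0.0076927)

#' Phenotypic Age linear predictor
#'
#' Computes the linear predictor `xb` from the nine biomarkers and
#' chronological age, in the published units: albumin g/L, creatinine
#' umol/L, fasting glucose mmol/L, natural log of C-reactive protein in
#' mg/dL, lymphocyte percent of white cells, mean cell volume fL, red cell
#' distribution width %, alkaline phosphatase U/L, white blood cell count
#' 1000 cells/uL, chronological age in years.
#'
#' All arguments are vectorized and recycled to a common length. Missing
#' values are an error: the score is undefined unless every input is present.
#'
#' @param albumin,creatinine,glucose,ln_crp,lymphocyte_pct,mcv,rdw,alk_phos,wbc
#'   biomarker vectors in the units above.
#' @param ca chronological age in years.
#' @return Numeric vector of `xb` values (unitless).
#' @export
phenoageXb <- function(albumin, creatinine, glucose, ln_crp, lymphocyte_pct,
                       mcv, rdw, alk_phos, wbc, ca) {
  args <- list(albumin = albumin, creatinine = creatinine, glucose = glucose,
               ln_crp = ln_crp, lymphocyte_pct = lymphocyte_pct, mcv = mcv,
               rdw = rdw, alk_phos = alk_phos, wbc = wbc, ca = ca)
  n <- max(vapply(args, length, 1L))
  args <- lapply(args, rep_len, n)
  bad <- names(args)[vapply(args, function(a) anyNA(a) || !is.numeric(a), TRUE)]
  if (length(bad))
    stop("missing or non-numeric Phenotypic Age inputs: ", paste(bad, collapse = ", "))
  -19.907 - 0.0336 * args$albumin + 0.0095 * args$creatinine +
    0.1953 * args$glucose + 0.0954 * args$ln_crp - 0.0120 * args$lymphocyte_pct +
    0.0268 * args$mcv + 0.3306 * args$rdw + 0.00188 * args$alk_phos +
    0.0554 * args$wbc + 0.0804 * args$ca
}

#' Phenotypic Age from the linear predictor
#'
#' The published transform is a nested Gompertz expression,
#' `PA = 141.50 + ln(-0.00553 * ln(exp(-1.51714 * exp(xb) / 0.0076927))) / 0.09165`,
#' which collapses algebraically to an affine function of `xb`:
#' `PA = 141.50 + (xb + ln(0.00553 * 1.51714 / 0.0076927)) / 0.09165`.
#' The nested form underflows in double precision once `exp(xb)` is large
#' enough to drive the inner `exp()` to zero (around `xb > -3.5`), so the
#' algebraically identical affine form is used for computation.
#'
#' @param xb linear predictor from [phenoageXb()].
#' @return Phenotypic Age in years.
#' @export
phenoage <- function(xb) {
  if (!is.numeric(xb) || anyNA(xb) || any(!is.finite(xb)))
    stop("xb must be finite and non-missing")
  k <- .pa_const
  k$a + (xb + log(k$g1 * k$g2 / k$g3)) / k$b
}

#' Phenotypic Age from cohort columns
#'
#' Convenience wrapper applying [phenoageXb()] and [phenoage()] to a cohort
#' table using the standard column names (see [cohortColumns()]).
#'
#' @param data data.frame with columns `albumin`, `creatinine`,
#'   `fasting_glucose`, `ln_crp`, `lymphocyte_pct`, `mcv`, `rdw`, `alk_phos`,
#'   `wbc`, `ca`.
#' @return Numeric vector of Phenotypic Ages in years.
#' @export
phenoageScore <- function(data) {
  phenoage(phenoageXb(
    albumin = data$albumin, creatinine = data$creatinine,
    glucose = data$fasting_glucose, ln_crp = data$ln_crp,
    lymphocyte_pct = data$lymphocyte_pct, mcv = data$mcv, rdw = data$rdw,
    alk_phos = data$alk_phos, wbc = data$wbc, ca = data$ca
  ))
}

#' Phenotypic age acceleration
#'
#' Acceleration is defined as the aging measure exceeding chronological age
#' (strictly greater; equality is not acceleration).
#'
#' @param pa Phenotypic Age in years.
#' @param ca chronological age in years.
#' @return Logical vector.
#' @export
phenoageAcceleration <- function(pa, ca) pa > ca
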