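# Shared fixtures built in code.

# an iid "design": equal weights, every record its own PSU, one stratum
iid_design <- function(n, weight = 1) {
  surveyDesign(stratum = rep(1, n), psu = seq_len(n),
               weight = rep(weight, n))
}

# small clustered design: n records over n_strata strata x 2 PSUs
toy_design <- function(n, n_strata = 4, seed = 1) {
  set.seed(seed)
  surveyDesign(stratum = sample(n_strata, n, TRUE),
               psu = sample(2, n, TRUE),
               weight = runif(n, 0.5, 2))
}

# brute-force Mann-Whitney pair-counting AUC (optionally weighted)
pair_count_auc <- function(scores, labels, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(scores))
  ci <- which(labels == 1); co <- which(labels == 0)
  num <- 0; den <- 0
  for (i in ci) for (j in co) {
    wij <- weights[i] * weights[j]
    num <- num + wij * (if (scores[i] > scores[j]) 1
                        else if (scores[i] == scores[j]) 0.5 else 0)
    den <- den + wij
  }
  num / den
}

# Literal nested Phenotypic Age transform. The fully naive evaluation is
# double-precision-accurate only on a middle band of xb: below about -19
# the inner log(exp(w)) with |w| ~ 1e-11 suffers catastrophic cancellation,
# and above about +1 exp(w) underflows to 0. phenoage_nested() therefore
# evaluates the inner log-of-exp composition exactly (log(exp(w)) = w, an
# identity, not an algebraic rearrangement of the rest of the formula) while
# keeping the outer nesting literal; phenoage_nested_naive() is the fully
# naive path for use inside its validity band.
phenoage_nested <- function(xb) {
  w <- -1.51714 * exp(xb) / 0.0076927
  141.50 + log(-0.00553 * w) / 0.09165
}
phenoage_nested_naive <- function(xb) {
  141.50 + log(-0.00553 * log(exp(-1.51714 * exp(xb) / 0.0076927))) / 0.09165
}

# 10-record exclusion fixture: 2 lack both eye grades, 1 lacks PIR,
# 1 lacks BMI, 6 complete
exclusion_fixture <- function() {
  d <- data.frame(
    id = 1:10,
    etdrs_left = c(NA, NA, rep(10, 8)),
    etdrs_right = c(NA, NA, rep(10, 8)),
    pir = c(rep(2, 2), NA, rep(2, 7)),
    bmi = c(rep(25, 3), NA, rep(25, 6))
  )
  steps <- list(
    imaging_biomarkers = function(x) is.na(x$etdrs_left) & is.na(x$etdrs_right),
    demographics = "pir",
    covariates = "bmi"
  )
  list(data = d, steps = steps)
}
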