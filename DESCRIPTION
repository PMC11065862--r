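Package: bioagedr
Title: Biological-Age Clocks and Survey-Weighted Risk Models for Diabetic Retinopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two clinical-biomarker aging clocks (the Klemera-Doubal
    biological age and the mortality-hazard-derived Phenotypic Age), cohort
    derivation rules for NHANES-style examination data (diabetes and diabetic
    retinopathy classification, blood-pressure averaging, exclusion cascades),
    design-based survey statistics (Horvitz-Thompson descriptives, Rao-Scott
    corrected chi-squared tests, survey-weighted logistic regression with
    Taylor-linearized variance), restricted-cubic-spline dose-response curves,
    ROC and decision-curve evaluation, and a synthetic cohort generator with a
    latent biological-aging process and known effect sizes so that the whole
    pipeline can be exercised end-to-end with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
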