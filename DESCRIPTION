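Package: progval
Title: External Validation of Probabilistic Prognostic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for externally validating models that output individual
    outcome probabilities, built around binary 10-year survival prediction
    in early breast cancer. Implements logistic recalibration with a joint
    intercept/slope calibration test suited to small cohorts, subgroup
    agreement tables of mean predicted versus observed survival, offset
    logistic regression (prediction logit entered with coefficient fixed
    at 1) to quantify the added prognostic value of candidate markers,
    predictive inaccuracy and explained variation with bootstrap standard
    errors, and rank-based AUC with an asymptotic confidence interval.
    Includes a synthetic cohort generator with controllable true
    calibration, subgroup miscalibration and covariate effects, emulating
    two published validation cohorts so the whole pipeline can be
    exercised without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
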