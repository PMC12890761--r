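Package: nephrarisk
Title: Literature-Informed 36-Month Diabetic Kidney Disease Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-year diabetic kidney disease (DKD/DN) risk engine built
    from published literature effect sizes, together with the full pipeline
    around it: a synthetic registry-cohort generator with proportional-hazards
    event times and administrative censoring, Bayesian chained imputation of
    fully-missing covariates from literature priors with Gelman-Rubin and
    posterior-predictive diagnostics, a stacked binary-plus-survival ensemble
    with isotonic calibration, and a survival-aware evaluation suite (IPCW
    time-dependent AUROC, Uno's C, decile calibration, decision-curve net
    benefit, bootstrap optimism, fairness audit, prediction-interval
    stability, drift flags).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
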