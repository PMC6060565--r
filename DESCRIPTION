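Package: strokebbn
Title: Bayesian Network Profiles of Sleep, Physical Activity and
    Self-Reported Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete Bayesian belief network pipeline for categorical
    health-survey data: deterministic binning of sleep and physical
    activity reports, naive Bayes and tree-augmented naive Bayes (Chow-Liu)
    structure learning with minimum description length model selection,
    smoothed conditional probability estimation, model-based imputation of
    missing responses, exact posterior inference with fixed-probability
    (covariate-standardized) and dynamic observational query modes,
    mutual-information association screening, classifier validation
    (precision, reliability, ROC index, lift index), and enumeration of
    sleep-by-activity risk profiles against a prevalence threshold.
    Includes a seeded generator of NHIS-like synthetic survey data so the
    whole pipeline is testable without microdata access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
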