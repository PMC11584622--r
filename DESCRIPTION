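Package: svmewma
Title: Risk-Adjusted EWMA Control Charts for Post-Surgery Survival Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Risk-adjusted one-sided exponentially weighted moving average
    (EWMA) control charts for monitoring survival time after surgery. Survival
    times are risk-adjusted for patient mix (Parsonnet score) either through a
    censored accelerated failure time regression (the RAEWMA chart) or through
    epsilon-insensitive support vector regression (the SVM-EWMA chart); the
    standardized residuals are monitored with a lower-one-sided clipped EWMA
    statistic with a time-varying lower control limit. Includes a Monte-Carlo
    run-length engine (ARL, SDRL and run-length percentiles; control-limit
    calibration to a target in-control ARL over a grid of residual shifts), a
    synthetic cardiac-surgery cohort generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    kernlab,
    jsonlite,
    survival,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
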