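Package: lcriskval
Title: Validation Toolkit for Lung Cancer Screening Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a comparative validation pipeline for absolute-risk
    prediction models used to select candidates for lung cancer screening.
    Provides config-driven implementations of nine published-model structures
    (PLCOm2012 and simplified variant, Liverpool Lung Project and simplified
    variant, Bach, Knoke, and three two-stage clonal expansion hazard models),
    calibration and discrimination metrics (calibration intercept/slope, AUC
    with DeLong confidence intervals), decision-curve analysis against
    pack-year-based eligibility criteria, count-matched risk thresholds,
    multiple imputation by chained equations with Rubin's-rules pooling, and a
    synthetic cohort generator emulating the risk-factor structure of the
    NLST and PLCO screening trials so that every pipeline stage is testable
    without access-restricted trial microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    deSolve
Config/testthat/edition: 3
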