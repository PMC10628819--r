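Package: sstpredict
Title: Prediction Models for Repeat Short Synacthen Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Develops, evaluates and applies multivariable prediction models
    for the outcome of a repeat ACTH stimulation test (short Synacthen test)
    from a new early-morning baseline cortisol combined with a patient's
    previous test results. Implements fractional-polynomial linear models
    with bootstrap variable selection, random-forest imputation,
    parameter-wise shrinkage and bootstrap-inclusion-fraction retention;
    calibration, discrimination (ROC) and cross-validation statistics;
    an equivocal-range decision policy quantifying the proportion of
    stimulation tests saved; and a synthetic paired-test cohort generator
    for fully reproducible simulation studies. Includes the published
    calculator models with fixed coefficients.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
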