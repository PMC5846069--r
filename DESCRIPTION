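Package: crcriskval
Title: External Validation of Colorectal Cancer Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for externally validating published risk prediction
    models for incident colorectal cancer in cohort data. Risk models are
    represented declaratively (logistic, Cox, simple point scores and
    relative-risk products), scored over harmonized participant records,
    converted between absolute-risk horizons under constant or doubling
    hazard assumptions, and assessed for discrimination (AUC with DeLong
    confidence intervals, Harrell's C, risk-stratified threshold metrics)
    and calibration (decile tables with Hosmer-Lemeshow statistics). A
    synthetic cohort generator emulating the risk-factor marginals of a
    large UK population-based cohort supports end-to-end testing of every
    pipeline stage, and a sensitivity-analysis battery covers extreme-case
    imputation, term dropping, surveillance exclusion and open-cohort
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    survival,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
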