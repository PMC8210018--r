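Package: prognosig
Title: Prognostic Expression Signatures by Bootstrap LASSO Cox Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies gene- or transcript-level prognostic signatures from
    high-dimensional expression data by bootstrap resampling of feature
    groups, each fitted with a 10-fold cross-validated LASSO-penalized Cox
    model, and aggregates per-iteration coefficients into a signature.
    Signatures are then validated by a per-sample linear risk score,
    median or ROC/Youden cut-point stratification, Kaplan-Meier estimation,
    log-rank testing, and univariate or clinically adjusted multivariate Cox
    models, including a patient-oriented bootstrap that measures how often
    each clinical covariable remains associated with the endpoint. Includes
    preflight filters (cohort viability, endpoint variability, variance,
    univariate Schoenfeld proportional-hazards screening, per-iteration
    Spearman collinearity vetting), a synthetic survival-cohort simulator
    with known ground truth, and plot-ready reporting outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
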