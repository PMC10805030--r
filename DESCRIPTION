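Package: polyomics
Title: Poly-Omic Risk Scores for Multi-Omic Disease Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-omic-layer disease risk scores from longitudinal
    multi-omic cohorts (metagenomic, metatranscriptomic, viromic and
    metabolomic feature tables) and combines them into a multi-omic
    prediction model. Implements compositional normalization (centered
    log-ratio), sparsity/collinearity/variance feature filtering,
    L1-penalized mixed-effects logistic regression with a lambda path and
    elbow selection, unpenalized mixed-model refitting, weighted-sum risk
    scoring with participant-level averaging, a leakage-free participant
    train/validation split, and evaluation via AUC (DeLong confidence
    intervals), odds ratios per standard deviation, and Nagelkerke's
    pseudo R-squared. A synthetic longitudinal cohort generator with
    planted feature effects makes every stage testable end to end, and a
    KEGG-orthology set-logic module classifies selected metabolites by
    likely host/microbial origin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    pROC,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
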