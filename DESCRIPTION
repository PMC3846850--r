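Package: ersvm
Title: Feature-Selecting Support Vector Machines for Estrogen Receptor
    Status Classification from Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning small gene-expression classifiers of breast
    tumor estrogen-receptor (ER) status. Implements non-parametric
    Parzen-window mutual information between continuous expression values and
    a binary phenotype, minimum-redundancy / maximum-relevance (mRMR) feature
    ranking, a feature-selecting linear support vector machine wrapper that
    picks the model size by a one-standard-deviation rule over stratified
    cross-validation folds, the four-step microarray normalization chain
    (intensity flooring, per-array and per-feature median scaling, per-feature
    z-scores) used to prepare single-channel arrays, a published fixed
    three-gene ER-status classifier with cross-platform probe mapping, and a
    synthetic cohort generator with planted informative features for
    benchmarking the whole pipeline without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
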