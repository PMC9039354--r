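Package: liverfair
Title: Sex-Stratified Fairness Audits of Liver-Disease Classifiers
Version: 0.1.0
Authors@R: person("liverfair", "maintainers", email = "maintainers@liverfair.org", role = c("aut", "cre"))
Description: Tools for auditing binary liver-disease classifiers for sex bias on
    cohorts shaped like the Indian Liver Patient Dataset (ILPD). Provides an
    ILPD-dialect CSV reader and cohort data model, the standard preparation steps
    (mean imputation, 0/1 sex encoding, target recoding, min-max normalisation),
    a from-scratch SMOTE oversampler with class- and sex-balancing schemes,
    sex-stratified feature exploration (Pearson ranking, IQR profiles) and
    recursive feature elimination, four classifier families (random forest,
    logistic regression, RBF support vector machine, Gaussian naive Bayes),
    per-sex confusion-matrix metrics and rank-based ROC AUC, male-minus-female
    disparity statistics with paired t-tests over repeated train/test runs, and
    a seeded synthetic cohort generator with a controllable sex-differential
    disease signal so the whole audit is exercisable without the real dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    FNN,
    quadprog
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
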