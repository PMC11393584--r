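Package: psychnet
Title: Psychometric Network Analysis of Ordinal Questionnaire Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and comparison of regularized partial-correlation
    (Gaussian graphical model) networks for ordinal questionnaire data, as
    used in symptom-network psychometrics. Implements graphical lasso
    estimation over a penalty path with extended-BIC model selection, node
    centrality indices (strength, closeness, betweenness, expected
    influence), case-dropping bootstrap stability (CS-coefficient),
    permutation-based network comparison (structure statistic M and global
    strength statistic S) with per-edge invariance tests, and bridge
    centrality across item communities. Includes a synthetic two-group
    Likert-data generator that plants sparse partial-correlation networks
    with controlled edge edits and a global-strength gap, plus scoring and
    group classification utilities for the GSES and PHQ-9 instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
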