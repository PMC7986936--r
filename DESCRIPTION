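Package: hdprog
Title: Hierarchical Bayesian Dynamical Models of Regional Brain Atrophy in
    Huntington's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Subject-level linear dynamical-systems models of longitudinal
    regional brain volumes around Huntington's disease motor onset, inverted
    by variational Laplace and pooled with parametric empirical Bayes over a
    covariate design matrix. Includes Bayesian model selection across four
    candidate state models, Bayesian model reduction and averaging with
    posterior-probability thresholding, interregional-connectivity
    comparisons, leave-one-out covariate prediction, nonhierarchical
    decade-loss summaries, brain-behaviour readout fitting, and a calibrated
    synthetic conversion-aligned cohort generator so the full analysis runs
    without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
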