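Package: msplspm
Title: Multiset Sparse Partial Least Squares Path Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Penalized multi-block latent-variable modeling for integrating
    several high-dimensional data sources measured on the same samples.
    Symmetric and asymmetric dependencies between data sources are encoded in
    a binary connectivity matrix and estimated with an iterative partial least
    squares path-modeling scheme in which outer weights of explanatory blocks
    are regularized by the Elastic Net or its univariate soft-thresholding
    limit, yielding sparse sets of selected variables. Includes k-fold
    cross-validation of the sparsity penalty, permutation tests of model
    significance, bootstrap confidence intervals for the objective function,
    extraction of successive orthogonal latent variables by residualization,
    and a synthetic-data generator with a replicated recovery study
    (true-positive/true-negative rates of variable selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
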