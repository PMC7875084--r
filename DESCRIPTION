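Package: wishartscore
Title: Wishart Null-Model Scoring and Classification of Covariance Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores symmetric positive-definite matrices (covariance or
    correlation matrices of multivariate time series) against class-wise
    Wishart null models. Each sample is represented by its p x p matrix and
    the number of observations behind it; class scale matrices are estimated
    as (length-weighted) averages of member matrices with leave-one-out or
    k-fold exclusion, and every sample receives a complete-matrix
    log-likelihood-ratio score plus per-feature scores obtained by principal
    submatrix deletion. The resulting score vectors form a feature
    transformation for supervised classification of unevenly sampled
    multivariate time series, with utilities for batch segmentation of
    labeled series, synthetic data generation, feature ranking, and
    cross-validated performance curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    foreign,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
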