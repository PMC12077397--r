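Package: adasplit
Title: Adaptive Discovery/External-Validation Sample Splitting for
    Prospective Predictive Modeling Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and replaying prospective predictive
    modeling studies in which a fixed sample-size budget must be split
    between model discovery and external validation. Implements a
    customizable stopping rule that combines hard sample-size thresholds,
    bootstrapped learning-curve analysis with tangent extrapolation of the
    expected full-budget performance, and a bootstrapped permutation-test
    power analysis of the prospective validation sample. Includes reference
    ridge and L2-regularized logistic estimators with nested cross-validated
    tuning, a replay harness comparing the adaptive rule against fixed
    splits, synthetic dataset generators with controllable learning-curve
    shapes, and a registered-model freeze/verify utility for preregistered
    external validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    digest,
    data.table,
    dplyr,
    tibble,
    pracma,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
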