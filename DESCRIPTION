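Package: recallcurve
Title: Learning-Curve Modelling and Discriminant Classification of
    CVLT-II Free Recall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a first-order transfer-function learning curve
    Y = B3*exp(-B2*(X-1)) + B4*(1-exp(-B2*(X-1))) to CVLT-II List A
    trials 1-5 free-recall counts, with asymptotic standard errors and
    R-squared; partitions subjects into lower/higher memory-functioning
    clusters by exact one-dimensional two-means on a model coefficient or
    by Ward's method on the raw trial scores; builds two-group Fisher
    linear discriminant functions with Wilks' lambda, Bartlett chi-square,
    a boundary value and predictor-space impairment cutoffs; and
    orchestrates the full gender-stratified pipeline for identifying
    overall memory impairment in multiple sclerosis, including a seeded
    synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
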