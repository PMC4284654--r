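Package: pcitr
Title: Neural Evidence Decoding and Plasticity-Curve Induction for
    Subsequent-Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating working-memory neural dynamics to later
    recognition memory. Provides multivoxel pattern analysis (MVPA) of
    region-of-interest fMRI timeseries with L2-penalized logistic
    classifiers and block-wise cross-validation; a Bayesian
    curve-induction procedure (P-CIT) that estimates the piecewise-linear
    "plasticity curve" linking classifier evidence to graded memory
    outcomes by importance sampling, with log Bayes factor scoring of the
    non-monotonic plasticity hypothesis; permutation and
    participant-bootstrap inference; and a synthetic-study generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
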