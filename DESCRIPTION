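Package: nof1serial
Title: Serial t-Tests for N-of-1 Trials with AR(1) Correlation
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Level-change and rate-change t-tests for single-individual
    (N-of-1) trials whose repeated observations carry first-order
    autoregressive serial correlation. Implements closed-form variance and
    bias kernels for ordinary-least-squares estimates under an AR(1)
    working correlation, the Fuller bias-corrected lag-1 correlation
    estimator, four serial t-tests with fractional degrees of freedom
    (paired and 2-sample, level and rate), their classical analogues,
    study-planning calculators (expected margin of error and detectable
    effect size at given power), and a Monte Carlo harness for Type I
    error, power and confidence-interval evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
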