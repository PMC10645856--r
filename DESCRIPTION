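Package: rrtvar
Title: Variance Estimation for Sensitive Variables under Scrambled
    Randomized Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the finite-population variance of a
    sensitive study variable from scrambled randomized-response (RRT)
    survey data. Implements the Diana-Perri multiplicative-additive
    scrambling model and a generalized mixture scrambling model, the
    associated decoding, ratio, generalized-ratio and exponential-type
    variance estimators with two auxiliary variables, closed-form
    first-order bias and mean-squared-error theory with optimum
    estimator constants, a generic delta-method oracle for validating
    the closed forms, respondent privacy-protection measures, and a
    seeded Monte-Carlo engine that reports empirical MSE, percent
    relative efficiency and the unified privacy-efficiency measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
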