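Package: gscaboot
Title: Bootstrap Confidence Intervals for Generalized Structured
    Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of generalized structured component analysis (GSCA)
    models by alternating least squares, with nonparametric bootstrap and
    jackknife resampling and three bootstrap confidence-interval methods
    (percentile, bias-corrected and accelerated, and Student's t) for every
    free loading and path coefficient.  Includes a population model for a
    six-component path structure with known explained variances, normal and
    lognormal-transformed synthetic data generators based on Cholesky mixing,
    and a Monte Carlo harness that scores interval coverage and balance
    against the population parameter values.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
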