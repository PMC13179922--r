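Package: ltrcks
Title: Omnibus k-Sample Tests for Left-Truncated Right-Censored Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kolmogorov-Smirnov and Cramer-von Mises type tests for the
    k-sample problem when survival data are subject to left truncation and
    right censoring.  Implements the product-limit estimator for
    left-truncated right-censored observations with an optional risk-set
    correction against premature holes, estimators of the truncation and
    residual-censoring distributions, an obvious-bootstrap resampling plan
    that approximates the null distribution of the test statistics, a family
    of weighted log-rank comparators, and a warp-speed Monte Carlo engine
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    MASS,
    jsonlite
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
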