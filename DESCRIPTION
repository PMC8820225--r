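Package: deltacv
Title: Interval Estimation for the Common Coefficient of Variation of
    Delta-Lognormal Populations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Point and interval estimation for the common coefficient of
    variation (CV) of several independent delta-lognormal (zero-inflated
    lognormal) populations, the standard model for semicontinuous data such
    as daily rainfall with exact-zero days.  Implements the fiducial
    generalized confidence interval (FGCI), equal-tailed and highest
    posterior density Bayesian credible intervals under independent
    Jeffreys and uniform priors, and the method of variance estimates
    recovery (MOVER), together with a Monte Carlo engine that measures the
    coverage probability and expected length of every method over a
    configurable scenario grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
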