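Package: weibullcm
Title: Interval Estimation for the Common Mean of Several Weibull Distributions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum likelihood estimation for two-parameter Weibull samples,
    delta-method variances of the fitted mean, and inverse-variance pooling of
    a common mean shared by several independent groups, together with four
    interval estimators for that common mean: a generalized confidence
    interval built from generalized pivotal quantities, an adjusted
    method-of-variance-estimates-recovery (MOVER) interval, and Bayesian
    equitailed and highest-posterior-density credible intervals from a Gibbs
    sampler with random-walk Metropolis updates of the shape parameter under
    gamma priors. Includes an AIC-based distribution comparison utility, a
    Monte Carlo engine for coverage-probability and expected-length studies,
    a command-line interface, and a bundled monthly wind-speed dataset from
    three districts of Surat Thani province, Thailand.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
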