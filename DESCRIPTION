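Package: nicomply
Title: Hypothetical Estimands in Non-Inferiority Trials with Non-Compliance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of hypothetical estimands in two-arm randomized
    non-inferiority trials with all-or-nothing non-compliance in both active
    arms. Implements intention-to-treat, per-protocol, inverse probability
    weighting with sandwich standard errors, two-stage least squares with a
    treatment-by-covariate interaction instrument, and a Bayesian instrumental
    variable estimator with an informative prior on the standard-treatment
    effect. Includes a trial simulator with named compliance scenarios, a
    non-inferiority decision rule, and a replicated simulation-study engine
    computing bias, precision, type-I error and replication-filtering rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    sandwich,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
RoxygenNote: 7.3.3
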