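Package: clpmscrutiny
Title: Scrutiny of Cross-Lagged Panel Effects with Complementary Structural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scrutinizing claimed prospective (cross-lagged) effects
    in two-wave panel studies. Given a study's sample size and the six
    correlations among a predictor and an outcome measured at two occasions,
    the package simulates standardized multivariate-normal data reproducing
    those correlations, fits four complementary structural models -- the
    cross-lagged panel model, its time-reversed variant, a latent change score
    model, and a second-order common-factor model of artifactualness with no
    direct predictor-outcome paths -- with a built-in maximum-likelihood
    structural-equation engine (RAM parameterization, analytic gradients,
    expected-information standard errors, CFI/TLI/RMSEA/SRMR fit indices), and
    classifies each claimed effect as consistent with a genuine effect,
    showing an artifactual pattern, or inconclusive, based on sign convergence
    across the complementary models. Includes data-generating processes with
    known truth (a genuine cross-lagged process and the artifactualness
    process) for validation and Monte-Carlo recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
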