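Package: lvcrm
Title: Latent Variable Count Regression Models with Latent Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Poisson and negative binomial regression with latent predictors
    measured by a linear common-factor model, including latent-by-latent and
    latent-by-manifest interaction terms. Parameters are estimated by marginal
    maximum likelihood, integrating the latent variables out of the case-wise
    likelihood with tensor-product Gauss-Hermite quadrature; gradients come
    from automatic differentiation ('TMB'). The package also provides the
    sum-score GLM comparison estimator, pointwise interaction effects defined
    as second-order mixed partial derivatives of the mean function with
    delta-method standard errors, conditional-regression (simple-slope)
    curves, and a seeded Monte-Carlo engine for bias, coverage, power and
    spill-over studies of both estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    TMB,
    jsonlite,
    numDeriv,
    optparse,
    statmod,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo,
    RcppEigen,
    TMB
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
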