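test_that("linear predictor assembles all active terms", {
  fx <- fixture_model(n = 30, seed = 7, study = 2)
  pp <- lvcrm:::empty_parameters(fx$model)
  pp$beta[] <- c(1.5, 0, 0, 0)
  expect_equal(linear_predictor(c(1, 0, 0, 0), c(0, 0), pp), 1.5)
  ## hand arithmetic: 0.5 + 0.2*2 + 0.3*1 + 0.1*(-1) + (-0.2)*1*(-1) = 1.3
  pp$beta[] <- c(0.5, 0.2, 0, 0)
  pp$gamma[] <- c(0.3, 0.1)
  pp$Gamma[1, 2] <- -0.2
  expect_equal(linear_predictor(c(1, 2, 0, 0), c(1, -1), pp), 1.3)
  ## single latent-manifest product
  pp2 <- lvcrm:::empty_parameters(fx$model)
  pp2$Omega[1, 1] <- 0.5
  expect_equal(linear_predictor(c(1, 2, 0, 0), c(1, 0), pp2), 1.0)
  expect_error(linear_predictor(c(1, 2), c(1, 0), pp), "length")
})

test_that("outcome log-densities match closed forms and the Poisson limit", {
  expect_equal(outcome_logdensity(0, 0, "poisson"), -1)
  expect_equal(outcome_logdensity(0, 0, "negbin", dispersion = 1), log(0.5))
  ## NB2 -> Poisson as dispersion -> Inf
  for (y in c(0, 3, 20))
    expect_equal(outcome_logdensity(y, log(3), "negbin", dispersion = 1e8),
                 outcome_logdensity(y, log(3), "poisson"), tolerance = 1e-6)
  expect_error(outcome_logdensity(-1, 0, "poisson"), "non-negative")
  expect_error(outcome_logdensity(1, 0, "negbin"), "dispersion")
})

test_that("indicator log-density matches a multivariate-normal oracle", {
  skip_if_not_installed("mvtnorm")
  fx <- fixture_model(n = 30, seed = 8)
  m <- fx$model
  expect_equal(indicator_logdensity(rep(0, 6), c(0, 0),
                                    lvcrm:::empty_parameters(m), m),
               6 * dnorm(0, log = TRUE))
  set.seed(21)
  for (i in 1:10) {
    pp <- random_params(m, 100 + i)
    w <- rnorm(m$q)
    eta <- rnorm(m$p)
    mu <- pp$nu + pp$lambda * eta[m$load_lat]
    oracle <- mvtnorm::dmvnorm(w, mu, diag(pp$theta), log = TRUE)
    expect_equal(indicator_logdensity(w, eta, pp, m), oracle,
                 tolerance = 1e-10)
  }
})

test_that("case-wise marginal likelihood agrees with Monte-Carlo integration", {
  fx <- fixture_model(n = 100, seed = 9, gamma_int = 0.3)
  m <- fx$model
  set.seed(31)
  n_checked <- 0
  for (r in 1:100) {
    i <- sample(m$n, 1)
    pp <- random_params(m, 200 + r)
    ## keep the random parameter draw in a numerically sane region
    pp$beta[1] <- pp$beta[1] * 0.5
    ll <- casewise_loglik(m$y[i], m$Z[i, ], m$W[i, ], pp, m, M = 15)
    mc <- mc_casewise(m$y[i], m$Z[i, ], m$W[i, ], pp, m,
                      draws = 20000, seed = 400 + r)
    expect_lt(abs(exp(ll) - mc$mean), 3 * mc$se + 1e-12)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 100)
})

test_that("with no latent variables the likelihood is the GLM likelihood", {
  set.seed(10)
  d <- data.frame(y = rpois(50, 3), z = rnorm(50))
  spec <- lvcrm_spec("y", covariates = "z")
  m <- validate_spec(spec, d)
  pp <- unpack_parameters(c(0.8, 0.25), m)
  expect_equal(total_loglik(m, pp),
               sum(dpois(d$y, exp(0.8 + 0.25 * d$z), log = TRUE)))
})

test_that("total log-likelihood is additive and row-order invariant", {
  fx <- fixture_model(n = 20, seed = 11)
  pp <- random_params(fx$model, 5)
  ll <- total_loglik(fx$model, pp)
  d2 <- rbind(fx$data, fx$data)
  expect_equal(total_loglik(validate_spec(fx$design$spec, d2), pp), 2 * ll,
               tolerance = 1e-10)
  d3 <- fx$data[rev(seq_len(nrow(fx$data))), ]
  expect_equal(total_loglik(validate_spec(fx$design$spec, d3), pp), ll,
               tolerance = 1e-10)
  ## indicator-order invariance: permuting indicator columns within a block
  spec_perm <- lvcrm_spec("y",
                          measurement = list(eta1 = c("w1_3", "w1_1", "w1_2"),
                                             eta2 = c("w2_2", "w2_3", "w2_1")),
                          interactions = list(c("eta1", "eta2")))
  m_perm <- validate_spec(spec_perm, fx$data)
  perm <- match(m_perm$indicators, fx$model$indicators)
  pp_perm <- pp
  pp_perm$nu <- pp$nu[perm]
  pp_perm$lambda <- pp$lambda[perm]
  pp_perm$theta <- pp$theta[perm]
  expect_equal(total_loglik(m_perm, pp_perm), ll, tolerance = 1e-10)
})

test_that("native and AD evaluators agree on value and gradient", {
  for (cfg in list(list(family = "poisson", study = 1, rel = c(.7, .9)),
                   list(family = "negbin", study = 2, rel = c(.8, .8)))) {
    fx <- fixture_model(n = 80, seed = 12, rel = cfg$rel,
                        family = cfg$family, study = cfg$study)
    sp <- lvcrm:::start_values(fx$model, fx$data)
    onat <- lvcrm:::native_objective(fx$model, sp, 7)
    oad <- lvcrm:::make_objective(fx$model, sp, 7)
    for (shift in c(0, 0.11)) {
      v <- onat$par + shift
      expect_equal(onat$fn(v), oad$fn(v), tolerance = 1e-9)
      expect_equal(unname(onat$gr(v)), as.numeric(oad$gr(v)),
                   tolerance = 1e-7)
    }
    ## and both match the plain-R mirror of the likelihood
    pp <- unpack_parameters(onat$par, fx$model)
    expect_equal(-onat$fn(onat$par), total_loglik(fx$model, pp, M = 7),
                 tolerance = 1e-8)
  }
})

test_that("the likelihood at the truth beats a distant parameter point", {
  fx <- fixture_model(n = 500, seed = 13, gamma_int = 0.3)
  m <- fx$model
  truth <- lvcrm:::empty_parameters(m)
  truth$beta[1] <- 0.2
  truth$gamma[] <- 0.3
  truth$Gamma[1, 2] <- 0.3
  truth$Sigma_eta <- fx$design$latent_cor
  truth$theta[] <- rep(fx$design$theta, each = 3)
  far <- truth
  far$gamma[] <- -1
  far$beta[1] <- 2
  expect_gt(total_loglik(m, truth), total_loglik(m, far))
})

test_that("more quadrature points stabilize the maximized log-likelihood", {
  fx <- fixture_model(n = 300, seed = 14, rel = c(.7, .7), gamma_int = -0.3)
  ll <- sapply(c(7, 15, 25), function(M)
    lvcrm_fit(fx$data, fx$design$spec, M = M, se = FALSE)$loglik)
  expect_lt(abs(ll[3] - ll[2]), abs(ll[2] - ll[1]))
})

test_that("a model without latent variables reduces to the GLM fit", {
  set.seed(15)
  d <- data.frame(y = rpois(300, 2), z1 = rnorm(300), z2 = rnorm(300))
  spec <- lvcrm_spec("y", covariates = c("z1", "z2"))
  f <- lvcrm_fit(d, spec, M = 1)
  g <- glm(y ~ z1 + z2, poisson, d)
  expect_equal(unname(coef(f)[1:3]), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$coefficients$se[1:3], unname(sqrt(diag(vcov(g)))),
               tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("parameter recovery on a large simulated dataset", {
  design <- sim_design(1, n = 2000, reliabilities = c(.8, .8),
                       gamma_int = 0.3)
  d <- simulate_lvcrm(design, seed = 16)
  f <- lvcrm_fit(d, design$spec, M = 9)
  expect_true(f$converged)
  tab <- f$coefficients
  for (par in c("gamma_eta1", "gamma_eta2", "gamma_eta1:eta2")) {
    row <- tab[tab$parameter == par, ]
    expect_lt(abs(row$estimate - 0.3), 3 * row$se)
  }
  row <- tab[tab$parameter == "cor_eta2.eta1", ]
  expect_lt(abs(row$estimate - 0.3), 3 * row$se)
})

test_that("Wald confidence intervals follow the normal quantile", {
  ## half-widths at levels .95 and .5; significance duality on a real fit
  fx <- fixture_model(n = 250, seed = 17, gamma_int = 0.3)
  f <- lvcrm_fit(fx$data, fx$design$spec, M = 7)
  ci <- wald_ci(f, parameters = "gamma_eta1:eta2")
  expect_equal(ci$upper - ci$estimate, 1.959964 * ci$se, tolerance = 1e-6)
  ci50 <- wald_ci(f, level = 0.5, parameters = "gamma_eta1:eta2")
  expect_equal(ci50$upper - ci50$estimate, 0.6744898 * ci50$se,
               tolerance = 1e-6)
  tab <- f$coefficients[f$coefficients$se > 0, ]
  expect_equal(tab$lower > 0 | tab$upper < 0,
               abs(tab$estimate / tab$se) > 1.959964)
  expect_error(wald_ci(f, parameters = "nope"), "unknown parameter")
})
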