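## a parameter view usable without any fitting
manual_ep <- function(beta, covariates = character(), gamma = numeric(0),
                      Gamma = NULL, Omega = NULL, latents = names(gamma)) {
  p <- length(gamma)
  list(beta = beta, gamma = gamma,
       Gamma = Gamma %||% matrix(0, p, p, dimnames = list(latents, latents)),
       Omega = Omega %||% matrix(0, p, length(covariates),
                                 dimnames = list(latents, covariates)),
       covariates = covariates, latents = latents,
       z_means = stats::setNames(rep(0, length(covariates)), covariates))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("expected count and marginal effects follow the chain rule", {
  ep <- manual_ep(beta = c("(Intercept)" = 0))
  expect_equal(expected_count(ep), 1)
  ep2 <- manual_ep(beta = c("(Intercept)" = log(2), z1 = 0.4),
                   covariates = "z1")
  expect_equal(expected_count(ep2), 2)
  expect_equal(expected_count(ep2, c(z1 = 1)), 2 * exp(0.4))
  expect_equal(marginal_effect(ep2, "z1", c(z1 = 0.5)),
               0.4 * exp(log(2) + 0.2))
  expect_error(marginal_effect(ep2, "z9"), "not a predictor")
})

test_that("the natural interaction appears without any product term", {
  ## pi = 0.5 + 0.3 z1 + 0.2 z2, no product: zeta = 0.3*0.2*exp(0.5)
  ep <- manual_ep(beta = c("(Intercept)" = 0.5, z1 = 0.3, z2 = 0.2),
                  covariates = c("z1", "z2"))
  expect_equal(interaction_effect(ep, "z1", "z2", c(z1 = 0, z2 = 0)),
               0.3 * 0.2 * exp(0.5), tolerance = 1e-12)
  expect_equal(interaction_effect(ep, "z1", "z2", c(z1 = 0, z2 = 0)),
               0.0989233, tolerance = 1e-6)
  expect_error(interaction_effect(ep, "z1", "z1"), "distinct")
})

test_that("analytic interaction effects match finite differences", {
  set.seed(41)
  for (r in 1:200) {
    beta <- c("(Intercept)" = rnorm(1, 0, .5), z1 = rnorm(1, 0, .4))
    gamma <- stats::setNames(rnorm(2, 0, .4), c("a", "b"))
    G <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    G["a", "b"] <- rnorm(1, 0, .3)
    Om <- matrix(rnorm(2, 0, .2), 2, 1,
                 dimnames = list(c("a", "b"), "z1"))
    ep <- manual_ep(beta, covariates = "z1", gamma = gamma, Gamma = G,
                    Omega = Om)
    pt <- c(a = rnorm(1), b = rnorm(1), z1 = rnorm(1))
    pair <- sample(c("a", "b", "z1"), 2)
    zeta <- interaction_effect(ep, pair[1], pair[2], pt)
    fd_fun <- function(x) {
      pt2 <- pt
      pt2[pair] <- x
      expected_count(ep, pt2)
    }
    fd <- numDeriv::hessian(fd_fun, pt[pair])[1, 2]
    expect_equal(zeta, fd, tolerance = 1e-5 * max(1, abs(fd)))
    ## marginal effect against the same oracle
    me <- marginal_effect(ep, pair[1], pt)
    g1 <- numDeriv::grad(function(x) fd_fun(c(x, pt[pair[2]])), pt[pair[1]])
    expect_equal(me, g1, tolerance = 1e-6 * max(1, abs(g1)))
  }
})

test_that("zeta vanishes with all-zero coefficients and keeps its sign law", {
  ep0 <- manual_ep(beta = c("(Intercept)" = 0), gamma = c(a = 0, b = 0))
  expect_equal(interaction_effect(ep0, "a", "b"), 0)
  ## sign equals sign of c_j c_k + b_jk (exp factor is positive)
  ep <- manual_ep(beta = c("(Intercept)" = 1), gamma = c(a = -0.4, b = 0.2))
  expect_lt(interaction_effect(ep, "a", "b", c(a = 0, b = 0)), 0)
})

test_that("delta-method SEs reduce to parameter SEs for linear effects", {
  fx <- fixture_model(n = 250, seed = 42, gamma_int = 0.3)
  f <- lvcrm_fit(fx$data, fx$design$spec, M = 7)
  se_g12 <- f$coefficients$se[f$coefficients$parameter == "gamma_eta1:eta2"]
  se1 <- delta_method_se(f, function(ep) ep$Gamma["eta1", "eta2"])
  expect_equal(se1, se_g12, tolerance = 1e-6)
  se2 <- delta_method_se(f, function(ep) 2 * ep$Gamma["eta1", "eta2"])
  expect_equal(se2, 2 * se_g12, tolerance = 1e-6)
})

test_that("delta-method zeta SEs agree with a parametric-simulation oracle", {
  fx <- fixture_model(n = 400, seed = 43, gamma_int = 0.3)
  f <- lvcrm_fit(fx$data, fx$design$spec, M = 7)
  pt <- c(eta1 = 0.5, eta2 = -1)
  est <- interaction_effect(f, "eta1", "eta2", pt, se = TRUE)
  ## draw free parameters from N(theta-hat, V), recompute zeta
  set.seed(44)
  ch <- chol(f$vcov)
  draws <- sapply(1:4000, function(i) {
    v <- f$par_free + drop(rnorm(length(f$par_free)) %*% ch)
    pp <- unpack_parameters(v, f$model)
    ep <- list(beta = pp$beta, gamma = pp$gamma, Gamma = pp$Gamma,
               Omega = pp$Omega, covariates = f$model$covariates,
               latents = f$model$latents,
               z_means = f$model$z_means)
    interaction_effect(ep, "eta1", "eta2", pt)
  })
  expect_lt(abs(sd(draws) - est$se) / est$se, 0.10)
})

test_that("conditional regression curves scale vertically when gamma12 = 0", {
  ep <- manual_ep(beta = c("(Intercept)" = 0.3),
                  gamma = c(a = 0.4, b = 0.25))
  cr <- conditional_regression(ep, "a", "b", moderator_values = c(-1, 1),
                               focal_values = c(-1, 0, 1), se = FALSE)
  lo <- cr$mu[cr$moderator == -1]
  hi <- cr$mu[cr$moderator == 1]
  ratio <- hi / lo
  expect_equal(ratio, rep(ratio[1], 3), tolerance = 1e-12)
  ## log-scale slopes equal, mu-scale slopes differ
  expect_equal(diff(log(lo)), diff(log(hi)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(diff(lo), diff(hi))))
  ## curves are the expected counts at the same points
  expect_equal(cr$mu[cr$moderator == 1 & cr$focal == 1],
               expected_count(ep, c(a = 1, b = 1)))
  ## monotone decreasing when the total focal coefficient is negative
  ep2 <- manual_ep(beta = c("(Intercept)" = 0), gamma = c(a = -0.5, b = 0))
  cr2 <- conditional_regression(ep2, "a", "b", moderator_values = 0,
                                focal_values = -2:2, se = FALSE)
  expect_true(all(diff(cr2$mu) < 0))
})

test_that("representative-point tables are symmetric and star by CI", {
  ## symmetric model: gamma1 = gamma2, exchangeable grid
  ep <- manual_ep(beta = c("(Intercept)" = 0.2),
                  gamma = c(a = 0.3, b = 0.3))
  tab <- conditional_regression(ep, "a", "b", moderator_values = -2:2,
                                focal_values = -2:2, se = FALSE)
  swapped <- tab
  for (r in seq_len(nrow(tab))) {
    mirror <- tab$zeta[tab$focal == tab$moderator[r] &
                         tab$moderator == tab$focal[r]]
    expect_equal(tab$zeta[r], mirror, tolerance = 1e-12)
  }
  ## stars on a fitted table follow the Wald duality, and the table is
  ## self-consistent with pointwise recomputation
  fx <- fixture_model(n = 300, seed = 45, gamma_int = 0.3)
  f <- lvcrm_fit(fx$data, fx$design$spec, M = 7)
  rp <- representative_points(f, values = c(-1, 0, 1))
  expect_equal(rp$significant, abs(rp$zeta / rp$se) > 1.959964)
  for (r in seq_len(nrow(rp))) {
    again <- interaction_effect(f, "eta1", "eta2",
                                c(eta1 = rp$j_value[r], eta2 = rp$k_value[r]))
    expect_equal(rp$zeta[r], again, tolerance = 1e-12)
  }
})
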