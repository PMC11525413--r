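test_that("validate_spec resolves dimensions and counts free parameters", {
  fx <- fixture_model(n = 50, seed = 2)
  m <- fx$model
  expect_equal(m$p, 2)
  expect_equal(m$q, 6)
  expect_equal(m$m, 0)
  ## standardized scaling: all nu/lambda/theta free, latent moments fixed
  expect_equal(sum(grepl("^nu_", m$par_names)), 6)
  expect_equal(sum(grepl("^lambda_", m$par_names)), 6)
  expect_equal(sum(grepl("^log_theta_", m$par_names)), 6)
  expect_false(any(grepl("^mu_|^log_sd_", m$par_names)))
  expect_equal(sum(grepl("^corr_tr_", m$par_names)), 1)
})

test_that("unidentified measurement blocks are rejected with a reason", {
  d <- data.frame(y = rpois(30, 2), w1 = rnorm(30), w2 = rnorm(30))
  spec <- lvcrm_spec("y", measurement = list(f = "w1"))
  expect_error(validate_spec(spec, d), "not identified")
  ## a fixed-reliability constraint restores identification
  spec_ok <- lvcrm_spec("y", measurement = list(f = "w1"),
                        fixed_reliability = c(w1 = 0.8))
  expect_s3_class(validate_spec(spec_ok, d), "lvcrm_model")
  ## two-indicator lone factor rejected, fine alongside a second factor
  spec2 <- lvcrm_spec("y", measurement = list(f = c("w1", "w2")))
  expect_error(validate_spec(spec2, d), "not identified")
})

test_that("outcome validation catches non-count outcomes", {
  d <- data.frame(y = c(1, 2.5, 3), w1 = rnorm(3))
  spec <- lvcrm_spec("y", covariates = "w1")
  expect_error(validate_spec(spec, d), "non-negative integer")
  expect_error(validate_spec(lvcrm_spec("nope"), d), "not found")
})

test_that("empirical-example layout enumerates the documented free slots", {
  ## 11 multi-indicator items + 1 fixed-reliability single indicator,
  ## both latents standardized, NB outcome with 3 manifest covariates
  set.seed(3)
  n <- 60
  d <- data.frame(y = rpois(n, 3), sex = rbinom(n, 1, .5), age = rnorm(n),
                  awe = rnorm(n))
  for (k in 1:11) d[[paste0("mdq", k)]] <- rnorm(n)
  d$tls <- rnorm(n)
  spec <- lvcrm_spec("y",
                     measurement = list(MD = paste0("mdq", 1:11), TL = "tls"),
                     covariates = c("sex", "age", "awe"),
                     interactions = list(c("MD", "TL")),
                     family = "negbin",
                     fixed_reliability = c(tls = 0.82))
  m <- validate_spec(spec, d)
  expect_equal(sum(grepl("^nu_", m$par_names)), 12)
  expect_equal(sum(grepl("^lambda_", m$par_names)), 12)
  expect_equal(sum(grepl("^log_theta_", m$par_names)), 11)  # tls constrained
  expect_equal(sum(grepl("^corr_tr_", m$par_names)), 1)
  expect_true("log_dispersion" %in% m$par_names)
})

test_that("fixed-reliability error variance follows lambda^2 (1/rel - 1)", {
  expect_equal(fixed_reliability_error_variance(1, 0.82), 1 / 0.82 - 1,
               tolerance = 1e-12)
  expect_equal(fixed_reliability_error_variance(1, 0.82), 0.2195122,
               tolerance = 1e-6)
  expect_equal(fixed_reliability_error_variance(1, 1), 0)
  expect_equal(fixed_reliability_error_variance(2, 0.5), 4)
  expect_error(fixed_reliability_error_variance(1, 0), "\\(0, 1\\]")
  expect_error(fixed_reliability_error_variance(1, 1.2), "\\(0, 1\\]")
})

test_that("parameter packing is a bijection on the free slots", {
  fx <- fixture_model(n = 40, seed = 4, family = "negbin")
  m <- fx$model
  n_free <- length(m$par_names)
  set.seed(11)
  for (i in 1:1000) {
    v <- stats::setNames(rnorm(n_free, sd = 0.7), m$par_names)
    v2 <- pack_parameters(unpack_parameters(v, m), m)
    expect_equal(v2, v, tolerance = 1e-10)
  }
})

test_that("the reliability constraint tracks its driver on every unpack", {
  set.seed(5)
  d <- data.frame(y = rpois(40, 2), w1 = rnorm(40), w2 = rnorm(40),
                  w3 = rnorm(40), s = rnorm(40))
  spec <- lvcrm_spec("y", measurement = list(a = c("w1", "w2", "w3"),
                                             b = "s"),
                     fixed_reliability = c(s = 0.82))
  m <- validate_spec(spec, d)
  v <- pack_parameters(lvcrm:::empty_parameters(m), m)
  i_lam <- which(m$par_names == "lambda_s")
  for (lam in c(0.5, 1, 1.7, -0.8)) {
    v[i_lam] <- lam
    pp <- unpack_parameters(v, m)
    expect_equal(pp$theta[["s"]], lam^2 * (1 / 0.82 - 1), tolerance = 1e-12)
  }
})

test_that("marker and standardized scalings give equivalent fits", {
  fx <- fixture_model(n = 250, rel = c(0.8, 0.8), gamma_int = 0.3, seed = 6)
  f_std <- lvcrm_fit(fx$data, fx$design$spec, M = 7, se = FALSE)
  f_mrk <- lvcrm_fit(fx$data, apply_scaling(fx$design$spec, "marker"),
                     M = 7, se = FALSE)
  expect_true(f_std$converged && f_mrk$converged)
  expect_equal(f_std$loglik, f_mrk$loglik, tolerance = 1e-4)
  ## structural estimates map onto each other: with eta* = (eta - mu)/s,
  ## gamma*_k = s_k (gamma_k + Gamma_kl mu_l) and Gamma*_12 = Gamma_12 s1 s2
  sd_mrk <- sqrt(diag(f_mrk$params$Sigma_eta))
  mu_mrk <- f_mrk$params$mu_eta
  g12 <- f_mrk$params$Gamma[1, 2]
  expect_equal(unname(f_std$params$gamma),
               unname(sd_mrk * (f_mrk$params$gamma +
                                  g12 * rev(mu_mrk))), tolerance = 2e-3)
  expect_equal(f_std$params$Gamma[1, 2], g12 * prod(sd_mrk),
               tolerance = 2e-3)
})
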