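test_that("reliability maps to the closed-form indicator error variance", {
  expect_equal(reliability_to_error_variance(0.7, c(1, 1, 1)),
               9 * 0.3 / (3 * 0.7), tolerance = 1e-12)
  expect_equal(reliability_to_error_variance(0.7, c(1, 1, 1)), 1.285714,
               tolerance = 1e-6)
  ## back-substitution: the implied sum-score reliability is the target
  th <- reliability_to_error_variance(0.7, c(1, 1, 1))
  expect_equal(9 / (9 + 3 * th), 0.7, tolerance = 1e-12)
  expect_equal(reliability_to_error_variance(1, c(1, 1, 1)), 0)
  expect_equal(reliability_to_error_variance(0.9, c(1, 1, 1)), 1 / 3,
               tolerance = 1e-9)
  expect_error(reliability_to_error_variance(0, c(1, 1)), "\\(0, 1\\]")
})

test_that("generated data reproduce the design moments", {
  design <- sim_design(1, n = 200000, reliabilities = c(0.7, 0.9),
                       gamma_int = 0)
  d <- simulate_lvcrm(design, seed = 55)
  eta <- attr(d, "truth")$eta
  expect_equal(cor(eta)[1, 2], 0.3, tolerance = 0.01)
  expect_equal(unname(apply(eta, 2, var)), c(1, 1), tolerance = 0.02)
  ## plug-in sum-score reliability: (sum lambda)^2 Var(eta) / Var(raw sum)
  for (dd in 1:2) {
    cols <- paste0("w", dd, "_", 1:3)
    rel_hat <- 9 / var(rowSums(d[, cols]))
    expect_equal(rel_hat, design$reliabilities[dd], tolerance = 0.01)
  }
})

test_that("a Poisson design with constant linear predictor is equidispersed", {
  design <- sim_design(1, n = 20000, reliabilities = c(.8, .8),
                       gamma_int = 0, gamma_main = 0, beta0 = 0.2)
  d <- simulate_lvcrm(design, seed = 56)
  expect_gt(var(d$y) / mean(d$y), 0.9)
  expect_lt(var(d$y) / mean(d$y), 1.1)
  ## the NB family with the same mean is overdispersed
  designN <- sim_design(1, n = 20000, reliabilities = c(.8, .8),
                        gamma_int = 0, gamma_main = 0, beta0 = 0.2,
                        family = "negbin")
  dN <- simulate_lvcrm(designN, seed = 56)
  expect_gt(var(dN$y) / mean(dN$y), 1.3)
})

test_that("study presets carry the documented structure", {
  d2 <- sim_design(2, n = 100, reliabilities = c(.8, .8), gamma_int = 0.1)
  expect_equal(d2$family, "negbin")
  expect_equal(d2$covariates, c("x1", "x2", "x3"))
  expect_equal(d2$beta_x, rep(0.2, 3))
  expect_equal(d2$dispersion, 2)
  d3 <- sim_design(3, gamma_int = "mixed", latent_cor = "mixed",
                   reliabilities = c(.7, .9, .7))
  expect_equal(d3$p, 3)
  expect_equal(d3$Gamma[upper.tri(d3$Gamma)], c(-0.3, 0.3, 0))
  expect_equal(d3$latent_cor[1, 2], -0.3)
  expect_equal(d3$latent_cor[2, 3], 0)
  expect_equal(length(true_parameters(d3)), 1 + 3 + 3)
  expect_error(sim_design(3, reliabilities = c(.8, .8, .8), gamma_int = 0.3,
                          latent_cor = "positive"), "3 values")
})

test_that("simulation runs are deterministic given the base seed", {
  design <- sim_design(1, n = 120, reliabilities = c(.8, .8),
                       gamma_int = 0.3)
  s1 <- run_simulation(design, R = 3, seed = 7, M = 7)
  s2 <- run_simulation(design, R = 3, seed = 7, M = 7)
  expect_identical(s1$estimates, s2$estimates)
  expect_false(identical(
    s1$estimates$estimate,
    run_simulation(design, R = 3, seed = 8, M = 7)$estimates$estimate))
  ## derived seeds are distinct and 32-bit safe
  seeds <- sapply(1:500, function(r) derive_seed(42, r))
  expect_equal(length(unique(seeds)), 500)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("single-replication metrics collapse to their definitions", {
  design <- sim_design(1, n = 150, reliabilities = c(.9, .9),
                       gamma_int = 0.3)
  s <- run_simulation(design, R = 1, seed = 9, estimators = "glm")
  m <- sim_metrics(s)
  row <- m[m$parameter == "gamma_eta1:eta2", ]
  est <- s$estimates$estimate[s$estimates$parameter == "gamma_eta1:eta2"]
  expect_equal(row$bias, est - 0.3)
  expect_equal(row$rmse, abs(est - 0.3))
  expect_true(row$coverage %in% c(0, 1))
})

test_that("aggregate metrics follow their formulas on constructed input", {
  est <- data.frame(
    estimator = "glm",
    parameter = "gamma_eta1:eta2",
    estimate = c(0.25, 0.35),
    se = 0.1, lower = c(0.25, 0.35) - 0.196, upper = c(0.25, 0.35) + 0.196,
    converged = TRUE, seed = 1:2, rep = 1:2)
  sim <- structure(list(estimates = est,
                        truth = c("gamma_eta1:eta2" = 0.3)),
                   class = "lvcrm_sim")
  m <- sim_metrics(sim)
  expect_equal(m$bias, 0)
  expect_equal(m$rmse, 0.05)
  expect_equal(m$coverage, 1)
  expect_equal(m$detection, 1)
  ## relative bias in percent
  sim$estimates$estimate <- c(0.27, 0.27)
  m2 <- sim_metrics(sim)
  expect_equal(m2$rel_bias, -10)
})

test_that("spill-over is the Euclidean norm of the biases", {
  expect_equal(spillover(c(0.003, 0.004, 0)), 0.005)
  expect_equal(spillover(c(0, 0, 0)), 0)
  b <- c(0.01, -0.02, 0.005)
  expect_equal(spillover(b), spillover(sample(b)))
})

test_that("both estimators recover the truth in a small smoke condition", {
  design <- sim_design(1, n = 500, reliabilities = c(.9, .9),
                       gamma_int = 0.3)
  ## high reliability means a tight posterior over eta, so the non-adaptive
  ## rule needs a finer grid here (see the methods vignette)
  s <- run_simulation(design, R = 50, seed = 31, M = 15)
  m <- sim_metrics(s)
  lv <- m[m$estimator == "lvcrm" & m$parameter == "gamma_eta1:eta2", ]
  mc_se <- m$rmse[m$estimator == "lvcrm" &
                    m$parameter == "gamma_eta1:eta2"] / sqrt(50)
  expect_lt(abs(lv$mean - 0.3), 3 * mc_se + 0.01)
  ## relative efficiency is reported for the product term
  expect_true(is.finite(attr(m, "rel_efficiency")[["gamma_eta1:eta2"]]))
  expect_equal(length(s$failed), 0)
})
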