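## shared fixture builders -- everything is generated in code at test time

## small two-latent Poisson dataset plus validated model and start values
fixture_model <- function(n = 200, rel = c(0.8, 0.8), gamma_int = 0.3,
                          family = "poisson", seed = 1, study = 1) {
  design <- sim_design(study = study, n = n, reliabilities = rel,
                       gamma_int = gamma_int, family = family)
  data <- simulate_lvcrm(design, seed = seed)
  model <- validate_spec(design$spec, data)
  list(design = design, data = data, model = model)
}

## Monte-Carlo oracle for the case-wise marginal likelihood:
## plain average of f(y|z,eta) f(w|eta) over draws eta ~ N(mu, Sigma)
mc_casewise <- function(y, z, w, params, model, draws = 20000, seed = 99) {
  set.seed(seed)
  p <- model$p
  eta <- matrix(stats::rnorm(draws * p), draws, p) %*%
    chol(params$Sigma_eta)
  eta <- sweep(eta, 2, params$mu_eta, "+")
  lt <- outcome_logdensity(y, linear_predictor(z, eta, params),
                           model$family, params$dispersion) +
    indicator_logdensity(w, eta, params, model)
  vals <- exp(lt)
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(draws))
}

## random natural-scale parameter set consistent with a model
random_params <- function(model, seed) {
  set.seed(seed)
  n_free <- length(model$par_names)
  v <- stats::rnorm(n_free, sd = 0.4)
  unpack_parameters(v, model)
}
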