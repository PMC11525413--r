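#' Linear predictor of the LV-CRM
#'
#' \eqn{\pi = z\beta + \gamma'\eta + \eta'\Gamma\eta + \eta'\Omega z} with
#' only the active product terms contributing. `eta` may be a matrix with
#' one latent vector per row (e.g. quadrature nodes), in which case a vector
#' of linear predictors is returned.
#'
#' @param z manifest covariate vector including the leading constant
#'   (length `m + 1`).
#' @param eta latent vector (length `p`) or a matrix (`G x p`).
#' @param params an `lvcrm_params` list (see [unpack_parameters()]).
#' @return numeric scalar (or vector, one per row of `eta`).
#' @export
linear_predictor <- function(z, eta, params) {
  z <- as.numeric(z)
  if (length(z) != length(params$beta))
    stop("'z' must have length ", length(params$beta),
         " (including the constant)")
  p <- length(params$gamma)
  if (p == 0L) {
    n_out <- if (is.null(dim(eta))) 1L else max(1L, nrow(eta))
    return(rep(sum(z * params$beta), n_out))
  }
  if (is.null(dim(eta))) eta <- matrix(as.numeric(eta), ncol = p)
  if (ncol(eta) != p) stop("'eta' must have ", p, " columns")
  out <- sum(z * params$beta) + drop(eta %*% params$gamma)
  if (any(params$Gamma != 0))
    out <- out + rowSums((eta %*% params$Gamma) * eta)
  if (length(params$Omega) && any(params$Omega != 0))
    out <- out + drop(eta %*% (params$Omega %*% z[-1L]))
  out
}

#' Log-density of the count outcome
#'
#' Poisson or NB2 log-density on the linear-predictor scale: the mean is
#' `exp(pi)`; under NB2 with size `dispersion` the variance is
#' `mu + mu^2/dispersion`.
#'
#' @param y count (vectorized).
#' @param pi linear predictor (vectorized).
#' @param family `"poisson"` or `"negbin"`.
#' @param dispersion NB size parameter (required for `"negbin"`).
#' @return log-density values.
#' @export
outcome_logdensity <- function(y, pi, family = c("poisson", "negbin"),
                               dispersion = NULL) {
  family <- match.arg(family)
  if (any(y < 0) || any(y != round(y)))
    stop("'y' must contain non-negative integers")
  if (family == "poisson")
    return(stats::dpois(y, exp(pi), log = TRUE))
  if (is.null(dispersion))
    stop("'dispersion' is required for the negative binomial family")
  stats::dnbinom(y, size = dispersion, mu = exp(pi), log = TRUE)
}

#' Log-density of the indicator vector given the latent variables
#'
#' Sum of univariate normal log-densities with means `nu + Lambda eta` and
#' variances `diag(Theta)` (congeneric structure: each indicator's mean
#' involves exactly one latent variable).
#'
#' @param w indicator vector (length `q`).
#' @param eta latent vector (length `p`) or matrix (`G x p`).
#' @param params an `lvcrm_params` list.
#' @param model an [validate_spec()] result (supplies the loading pattern).
#' @return log-density (scalar, or vector over rows of `eta`).
#' @export
indicator_logdensity <- function(w, eta, params, model) {
  if (any(params$theta <= 0))
    stop("all measurement error variances must be positive")
  if (is.null(dim(eta))) eta <- matrix(as.numeric(eta), ncol = model$p)
  out <- numeric(nrow(eta))
  for (k in seq_len(model$q)) {
    mean_k <- params$nu[k] + params$lambda[k] * eta[, model$load_lat[k]]
    out <- out + stats::dnorm(w[k], mean_k, sqrt(params$theta[k]), log = TRUE)
  }
  out
}

#' Case-wise marginal log-likelihood
#'
#' The latent variables are integrated out of the case-wise likelihood:
#' \deqn{\log \sum_j \omega_j f(y | z, \eta^*_j) f(w | \eta^*_j)}
#' evaluated with a log-sum-exp over the quadrature nodes. The linear
#' predictor (including all product terms) is formed at the integration
#' points themselves; products of latent variables never become extra
#' measurement parameters. With `p = 0` the sum collapses to the plain GLM
#' outcome log-density.
#'
#' @param y count outcome (scalar).
#' @param z covariate vector including the constant.
#' @param w indicator vector (length `q`; ignored when `p = 0`).
#' @param params an `lvcrm_params` list.
#' @param model an [validate_spec()] result.
#' @param grid an [product_grid()] built from the current `mu_eta`,
#'   `Sigma_eta`; defaults to a fresh grid with `M` points per dimension.
#' @param M points per dimension when `grid` is not supplied.
#' @return the case-wise marginal log-likelihood.
#' @export
casewise_loglik <- function(y, z, w, params, model, grid = NULL, M = 15) {
  if (model$p == 0L)
    return(outcome_logdensity(y, linear_predictor(z, numeric(0), params),
                              model$family, params$dispersion))
  if (is.null(grid))
    grid <- product_grid(M, params$mu_eta, params$Sigma_eta)
  lt <- log(grid$weights) +
    outcome_logdensity(y, linear_predictor(z, grid$nodes, params),
                       model$family, params$dispersion) +
    indicator_logdensity(w, grid$nodes, params, model)
  out <- logsumexp(lt)
  if (!is.finite(out))
    stop("case-wise likelihood underflowed at every node")
  out
}

#' Total marginal log-likelihood
#'
#' Sum of [casewise_loglik()] over all rows; the quadrature grid is rebuilt
#' from the current latent mean and covariance.
#'
#' @param data a data frame with all model columns, or an `lvcrm_model`.
#' @param params an `lvcrm_params` list.
#' @param model an [validate_spec()] result (omit when `data` is a model).
#' @param M quadrature points per dimension.
#' @return the total log-likelihood.
#' @export
total_loglik <- function(data, params, model = NULL, M = 15) {
  if (inherits(data, "lvcrm_model")) {
    model <- data
  } else {
    model <- validate_spec(model$spec %||% stop("'model' is required"),
                           data)
  }
  grid <- if (model$p)
    product_grid(M, params$mu_eta, params$Sigma_eta) else NULL
  ll <- 0
  for (i in seq_len(model$n)) {
    ll <- ll + casewise_loglik(model$y[i], model$Z[i, ],
                               if (model$q) model$W[i, ] else numeric(0),
                               params, model, grid = grid)
  }
  ll
}
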