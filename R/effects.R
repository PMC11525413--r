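## A fit-class-independent view of the structural parameters, used by all
## effect computations. For the GLM baseline the standardized sum scores
## play the role of the latent variables.
effect_params <- function(fit) {
  if (inherits(fit, "lvcrm_fit")) {
    m <- fit$model
    list(beta = fit$params$beta, gamma = fit$params$gamma,
         Gamma = fit$params$Gamma, Omega = fit$params$Omega,
         covariates = m$covariates, latents = m$latents)
  } else if (inherits(fit, "lvcrm_glm")) {
    ep_from_coefs(coef(fit), fit$spec)
  } else if (is.list(fit) && !is.null(fit$beta)) {
    fit
  } else stop("unsupported fit object")
}

ep_from_coefs <- function(cf, spec) {
  latents <- names(spec$measurement)
  covs <- spec$covariates
  p <- length(latents); m <- length(covs)
  beta <- stats::setNames(
    cf[c("beta_(Intercept)", if (m) paste0("beta_", covs))],
    c("(Intercept)", covs))
  gamma <- stats::setNames(
    if (p) cf[paste0("gamma_", latents)] else numeric(0), latents)
  Gamma <- matrix(0, p, p, dimnames = list(latents, latents))
  for (pr in spec$interactions)
    Gamma[pr[1], pr[2]] <- cf[[paste0("gamma_", pr[1], ":", pr[2])]]
  Omega <- matrix(0, p, m, dimnames = list(latents, covs))
  for (pr in spec$latent_covariate_interactions)
    Omega[pr[1], pr[2]] <- cf[[paste0("omega_", pr[2], ":", pr[1])]]
  list(beta = beta, gamma = gamma, Gamma = Gamma, Omega = Omega,
       covariates = covs, latents = latents)
}

## complete an evaluation point: covariates default to their sample means,
## latent variables to 0 (their identified mean on the standardized scale)
resolve_point <- function(fit, point = NULL) {
  ep <- effect_params(fit)
  zm <- if (inherits(fit, "lvcrm_fit")) fit$model$z_means else fit$z_means
  if (is.null(zm))
    zm <- stats::setNames(rep(0, length(ep$covariates)), ep$covariates)
  full <- c(stats::setNames(rep(0, length(ep$latents)), ep$latents),
            stats::setNames(as.numeric(zm[ep$covariates]), ep$covariates))
  if (!is.null(point)) {
    point <- unlist(point)
    bad <- setdiff(names(point), names(full))
    if (length(bad))
      stop("unknown predictor(s) in point: ", paste(bad, collapse = ", "))
    full[names(point)] <- point
  }
  full
}

ep_linpred <- function(ep, point) {
  z <- point[ep$covariates]
  eta <- point[ep$latents]
  out <- ep$beta[[1]] + sum(ep$beta[-1] * z) + sum(ep$gamma * eta)
  if (length(eta)) out <- out + drop(eta %*% ep$Gamma %*% eta)
  if (length(eta) && length(z)) out <- out + drop(eta %*% ep$Omega %*% z)
  unname(out)
}

## total first-order coefficient of predictor x at the point
ep_coef <- function(ep, x, point) {
  eta <- point[ep$latents]
  z <- point[ep$covariates]
  if (x %in% ep$latents) {
    k <- match(x, ep$latents)
    unname(ep$gamma[k] +
             sum((ep$Gamma[k, ] + ep$Gamma[, k]) * eta) +
             (if (length(z)) sum(ep$Omega[k, ] * z) else 0))
  } else if (x %in% ep$covariates) {
    j <- match(x, ep$covariates)
    unname(ep$beta[[j + 1L]] +
             (if (length(eta)) sum(ep$Omega[, j] * eta) else 0))
  } else stop("'", x, "' is not a predictor of the model")
}

## product-term coefficient attached to the pair (j, k)
ep_pair_coef <- function(ep, j, k) {
  if (j %in% ep$latents && k %in% ep$latents) {
    a <- match(j, ep$latents); b <- match(k, ep$latents)
    unname(ep$Gamma[a, b] + ep$Gamma[b, a])
  } else if (j %in% ep$latents && k %in% ep$covariates) {
    unname(ep$Omega[match(j, ep$latents), match(k, ep$covariates)])
  } else if (k %in% ep$latents && j %in% ep$covariates) {
    unname(ep$Omega[match(k, ep$latents), match(j, ep$covariates)])
  } else 0
}

#' Expected count at an evaluation point
#'
#' `exp(pi)` at the given values of the covariates and latent variables;
#' unspecified covariates sit at their sample means, unspecified latent
#' variables at 0.
#'
#' @param fit an `lvcrm_fit` or `lvcrm_glm` object.
#' @param point named vector/list of predictor values (latent variables on
#'   the identified latent scale).
#' @return the model-implied expected count.
#' @export
expected_count <- function(fit, point = NULL) {
  ep <- effect_params(fit)
  exp(ep_linpred(ep, resolve_point(fit, point)))
}

#' Marginal effect of a predictor
#'
#' First derivative of the mean function `exp(pi)` with respect to a
#' (continuous) predictor, evaluated analytically from the model's
#' polynomial structure: the total first-order coefficient of the predictor
#' at the point, times `exp(pi)`.
#'
#' @param fit an `lvcrm_fit` or `lvcrm_glm`.
#' @param x predictor name (manifest covariate or latent variable).
#' @param point named vector of predictor values (see [expected_count()]).
#' @return the marginal effect (scalar).
#' @export
marginal_effect <- function(fit, x, point = NULL) {
  ep <- effect_params(fit)
  pt <- resolve_point(fit, point)
  ep_coef(ep, x, pt) * exp(ep_linpred(ep, pt))
}

#' Pointwise interaction effect (second-order mixed partial derivative)
#'
#' The interaction effect of predictors `j` and `k` at a point is
#' \deqn{\zeta_{jk} = \frac{\partial^2 \exp(\pi)}{\partial x_j \partial x_k}
#'   = \exp(\pi)\,[c_j c_k + b_{jk}]}
#' where \eqn{c_j, c_k} are the total first-order coefficients at the point
#' and \eqn{b_{jk}} the product-term coefficient (zero if the product is
#' absent). Because the mean function is nonlinear, \eqn{\zeta_{jk}} can be
#' non-zero even without a product term (the "natural" or model-inherent
#' interaction), and it varies over the predictor space.
#'
#' @param fit an `lvcrm_fit` or `lvcrm_glm`.
#' @param j,k two distinct predictor names.
#' @param point named vector of predictor values (see [expected_count()]).
#' @param se if `TRUE`, also return the delta-method SE and Wald CI.
#' @param level confidence level for the CI.
#' @return scalar `zeta`, or (with `se = TRUE`) a one-row data frame with
#'   `zeta`, `se`, `lower`, `upper`.
#' @export
interaction_effect <- function(fit, j, k, point = NULL, se = FALSE,
                               level = 0.95) {
  if (identical(j, k)) stop("'j' and 'k' must be distinct predictors")
  pt <- resolve_point(fit, point)
  val_fn <- function(ep) {
    (ep_coef(ep, j, pt) * ep_coef(ep, k, pt) + ep_pair_coef(ep, j, k)) *
      exp(ep_linpred(ep, pt))
  }
  zeta <- val_fn(effect_params(fit))
  if (!se) return(zeta)
  sez <- delta_method_se(fit, val_fn)
  zq <- stats::qnorm((1 + level) / 2)
  data.frame(zeta = zeta, se = sez, lower = zeta - zq * sez,
             upper = zeta + zq * sez)
}

#' Delta-method standard error of a smooth function of the estimates
#'
#' `SE = sqrt(g' V g)` with `g` the numerical gradient of the effect with
#' respect to the free parameters at the estimates and `V` the estimated
#' covariance of the free parameters.
#'
#' @param fit a converged `lvcrm_fit` (or `lvcrm_glm`).
#' @param effect function of the structural-parameter view: a list with
#'   `beta`, `gamma`, `Gamma`, `Omega` (see the package vignette), returning
#'   a scalar.
#' @return the delta-method standard error.
#' @export
delta_method_se <- function(fit, effect) {
  if (inherits(fit, "lvcrm_fit")) {
    if (is.null(fit$vcov))
      stop("fit has no covariance matrix; refit with se = TRUE")
    model <- fit$model
    fn <- function(v) {
      pp <- unpack_parameters(v, model)
      effect(list(beta = pp$beta, gamma = pp$gamma, Gamma = pp$Gamma,
                  Omega = pp$Omega, covariates = model$covariates,
                  latents = model$latents))
    }
    g <- numDeriv::grad(fn, fit$par_free)
    V <- fit$vcov
  } else if (inherits(fit, "lvcrm_glm")) {
    cf <- coef(fit)
    cf <- cf[names(cf) != "dispersion"]
    fn <- function(v) effect(ep_from_coefs(stats::setNames(v, names(cf)),
                                           fit$spec))
    g <- numDeriv::grad(fn, as.numeric(cf))
    V <- fit$vcov
  } else stop("unsupported fit object")
  if (any(!is.finite(g))) stop("effect gradient is not finite")
  sqrt(drop(t(g) %*% V %*% g))
}

#' Conditional regression (simple-slope) curves
#'
#' The model-implied expected count as a function of a focal latent
#' variable, drawn at several values of a moderator (default -2 to 2 SD on
#' the identified latent scale), with the pointwise interaction effect
#' \eqn{\zeta} and its Wald CI along the curve; remaining covariates are
#' fixed at their sample means.
#'
#' @param fit a converged `lvcrm_fit` or `lvcrm_glm`.
#' @param focal name of the focal predictor (x-axis).
#' @param moderator name of the moderating predictor.
#' @param moderator_values values of the moderator (default `-2:2`).
#' @param focal_values grid for the focal predictor.
#' @param point optional named overrides for the remaining predictors.
#' @param se compute delta-method CIs for zeta (requires a covariance).
#' @param level confidence level.
#' @return data frame with columns `focal`, `moderator`, `mu`, `zeta`, and
#'   (with `se`) `se`, `lower`, `upper`, `significant`.
#' @export
conditional_regression <- function(fit, focal, moderator,
                                   moderator_values = -2:2,
                                   focal_values = seq(-2.5, 2.5, by = 0.25),
                                   point = NULL, se = TRUE, level = 0.95) {
  has_v <- (inherits(fit, "lvcrm_fit") && !is.null(fit$vcov)) ||
    inherits(fit, "lvcrm_glm")
  se <- se && has_v
  rows <- expand.grid(focal = focal_values, moderator = moderator_values)
  out <- lapply(seq_len(nrow(rows)), function(r) {
    pt <- c(stats::setNames(rows$focal[r], focal),
            stats::setNames(rows$moderator[r], moderator))
    if (!is.null(point)) pt <- c(pt, unlist(point))
    mu <- expected_count(fit, pt)
    z <- interaction_effect(fit, focal, moderator, pt, se = se,
                            level = level)
    if (se) cbind(data.frame(mu = mu), z) else
      data.frame(mu = mu, zeta = z)
  })
  out <- cbind(rows, do.call(rbind, out))
  if (se) out$significant <- out$lower > 0 | out$upper < 0
  out
}

#' Interaction effects at representative points
#'
#' \eqn{\zeta_{jk}} with delta-method Wald CIs on a grid of representative
#' values of the two predictors (default: means and 1 and 2 SD above/below,
#' i.e. -2, -1, 0, 1, 2 on the identified latent scale), remaining
#' covariates at their sample means. Cells whose CI excludes zero are
#' starred (two-sided Wald at `1 - level`, no multiplicity adjustment).
#'
#' @param fit a converged `lvcrm_fit` or `lvcrm_glm`.
#' @param j,k predictor names; default the model's first latent pair with a
#'   product term (or the first two latent variables).
#' @param values grid values for both predictors (default `-2:2`).
#' @param point optional named overrides for the remaining predictors.
#' @param level confidence level (default 0.95).
#' @return data frame of class `lvcrm_zeta_table` with one row per cell:
#'   `j_value`, `k_value`, `zeta`, `se`, `lower`, `upper`, `significant`.
#' @export
representative_points <- function(fit, j = NULL, k = NULL, values = -2:2,
                                  point = NULL, level = 0.95) {
  ep <- effect_params(fit)
  if (is.null(j) || is.null(k)) {
    spec <- if (inherits(fit, "lvcrm_fit")) fit$model$spec else fit$spec
    pr <- if (length(spec$interactions)) spec$interactions[[1]] else
      ep$latents[1:2]
    j <- j %||% pr[1]; k <- k %||% pr[2]
  }
  cells <- expand.grid(j_value = values, k_value = values)
  res <- lapply(seq_len(nrow(cells)), function(r) {
    pt <- c(stats::setNames(cells$j_value[r], j),
            stats::setNames(cells$k_value[r], k))
    if (!is.null(point)) pt <- c(pt, unlist(point))
    interaction_effect(fit, j, k, pt, se = TRUE, level = level)
  })
  out <- cbind(cells, do.call(rbind, res))
  out$significant <- out$lower > 0 | out$upper < 0
  attr(out, "predictors") <- c(j, k)
  class(out) <- c("lvcrm_zeta_table", class(out))
  out
}

#' @export
print.lvcrm_zeta_table <- function(x, digits = 3, ...) {
  pr <- attr(x, "predictors")
  cat("Interaction effects zeta(", pr[1], ", ", pr[2],
      ") at representative points (* : 95% CI excludes 0)\n", sep = "")
  vals_j <- sort(unique(x$j_value))
  vals_k <- sort(unique(x$k_value), decreasing = TRUE)
  M <- matrix("", length(vals_k), length(vals_j),
              dimnames = list(paste0(pr[2], "=", vals_k),
                              paste0(pr[1], "=", vals_j)))
  for (r in seq_len(nrow(x))) {
    M[paste0(pr[2], "=", x$k_value[r]), paste0(pr[1], "=", x$j_value[r])] <-
      paste0(format(x$zeta[r], digits = digits),
             if (isTRUE(x$significant[r])) "*" else "")
  }
  print(M, quote = FALSE, right = TRUE)
  invisible(x)
}
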