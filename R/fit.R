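## Two-step starting values: (i) measurement parameters from moments of the
## indicator blocks (principal-axis); (ii) structural parameters from the
## sum-score GLM baseline, with regression factor scores for the latent
## correlation start.
start_values <- function(model, data) {
  params <- empty_parameters(model)
  p <- model$p
  if (p) {
    scores <- matrix(0, model$n, p)
    for (d in seq_len(p)) {
      blk <- which(model$load_lat == d)
      Wb <- model$W[, blk, drop = FALSE]
      k <- length(blk)
      params$nu[blk] <- colMeans(Wb)
      if (k >= 2) {
        S <- stats::cov(Wb)
        e <- eigen(S, symmetric = TRUE)
        lam <- sqrt(max(e$values[1], 1e-4)) * e$vectors[, 1]
        if (sum(lam) < 0) lam <- -lam
        params$lambda[blk] <- lam
        params$theta[blk] <- pmax(diag(S) - lam^2, 0.05 * diag(S))
      } else {
        v <- stats::var(Wb[, 1])
        rel <- if (blk %in% model$rel_idx)
          model$rel_val[match(blk, model$rel_idx)] else 0.8
        params$lambda[blk] <- sqrt(v * rel)
        params$theta[blk] <- max(v * (1 - rel), 1e-3)
      }
      scores[, d] <- scale(Wb %*% (params$lambda[blk] / sum(params$lambda[blk]^2)))
    }
    if (p >= 2) {
      R <- stats::cor(scores)
      ## keep the start well inside the admissible region
      R[R > 0.95] <- 0.95; R[R < -0.95] <- -0.95
      diag(R) <- 1
      ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 1e-4) R <- diag(p)
      params$Sigma_eta <- R
    }
    if (model$scaling == "marker") {
      ## rescale the standardized-start solution to the marker convention
      first <- match(seq_len(p), model$load_lat)
      sd0 <- params$lambda[first]
      for (d in seq_len(p)) {
        blk <- which(model$load_lat == d)
        params$mu_eta[d] <- params$nu[first[d]]
        params$nu[blk] <- params$nu[blk] -
          params$lambda[blk] / sd0[d] * params$nu[first[d]]
        params$lambda[blk] <- params$lambda[blk] / sd0[d]
      }
      params$Sigma_eta <- diag(sd0, p) %*% params$Sigma_eta %*% diag(sd0, p)
    }
    colnames(scores) <- model$latents
  } else {
    scores <- NULL
  }
  ## structural starts from a GLM on covariates and factor scores
  df <- data.frame(.y = model$y, check.names = FALSE)
  if (model$m) df <- cbind(df, as.data.frame(model$Z[, -1L, drop = FALSE]))
  if (p) df <- cbind(df, as.data.frame(scores))
  terms <- c(model$covariates,
             if (p) model$latents,
             if (nrow(model$gi))
               paste0(model$latents[model$gi[, 1]], ":",
                      model$latents[model$gi[, 2]]),
             if (nrow(model$om))
               paste0(model$covariates[model$om[, 2]], ":",
                      model$latents[model$om[, 1]]))
  fml <- stats::as.formula(paste(".y ~",
                                 if (length(terms))
                                   paste(terms, collapse = " + ") else "1"))
  fit0 <- tryCatch({
    if (model$family == "poisson") stats::glm(fml, poisson(), data = df)
    else suppressWarnings(MASS::glm.nb(fml, data = df))
  }, error = function(e) NULL)
  if (!is.null(fit0) && all(is.finite(stats::coef(fit0)))) {
    cf <- stats::coef(fit0)
    params$beta[] <- cf[seq_len(model$m + 1L)]
    pos <- model$m + 1L
    if (p) params$gamma[] <- cf[pos + seq_len(p)]
    pos <- pos + p
    if (nrow(model$gi)) params$Gamma[model$gi] <- cf[pos + seq_len(nrow(model$gi))]
    pos <- pos + nrow(model$gi)
    if (nrow(model$om)) params$Omega[model$om] <- cf[pos + seq_len(nrow(model$om))]
    if (model$family == "negbin")
      params$dispersion <- min(max(fit0$theta, 0.05), 50)
  } else {
    params$gamma[] <- 0.1
    if (model$family == "negbin") params$dispersion <- 2
  }
  apply_constraints(params, model)
}

#' Fit a latent variable count regression model
#'
#' Maximizes the marginal likelihood of the LV-CRM: the latent variables
#' are integrated out of each case-wise likelihood with a tensor-product
#' Gauss-Hermite rule (the grid follows the current latent mean and
#' covariance at every iteration), and the objective and its exact analytic
#' gradient are evaluated in compiled code. Optimization uses the `PORT`
#' quasi-Newton routine ([stats::nlminb()]). Standard errors come from the
#' observed information, obtained by finite differences of the analytic
#' gradient at the optimum.
#'
#' Starting values follow a two-step scheme: measurement parameters from
#' moment (principal-axis) fits to the indicator blocks, structural
#' parameters from a count GLM on regression factor scores.
#'
#' @param data data frame with the outcome, covariate and indicator columns.
#' @param spec an [lvcrm_spec()].
#' @param M Gauss-Hermite points per latent dimension (default 15).
#' @param se compute standard errors (observed information); default `TRUE`.
#' @param start optional `lvcrm_params` list of starting values.
#' @param control list: `maxit` (default 500), `rel_tol` (relative change of
#'   the log-likelihood, default 1e-8), `grad_tol` (gradient infinity norm
#'   declared converged, default 1e-4).
#' @param engine `"native"` (hand-coded likelihood with analytic gradient;
#'   default, about an order of magnitude faster) or `"ad"` (automatic
#'   differentiation through 'TMB'). Both evaluate the identical marginal
#'   likelihood; the AD path is retained as an independent cross-check.
#' @return an object of class `lvcrm_fit`: parameter table
#'   (`$coefficients`), natural-scale parameters (`$params`), free-scale
#'   covariance (`$vcov`), `$loglik`, `$converged`, `$iterations`,
#'   `$grad_norm`, the validated `$model` and `$M`.
#' @examples
#' \donttest{
#' design <- sim_design(study = 1, n = 300, reliabilities = c(.8, .8),
#'                      gamma_int = 0.3)
#' d <- simulate_lvcrm(design, seed = 1)
#' fit <- lvcrm_fit(d, design$spec, M = 9)
#' coef(fit)["gamma_eta1:eta2"]
#' }
#' @export
lvcrm_fit <- function(data, spec, M = 15, se = TRUE, start = NULL,
                      control = list(), engine = c("native", "ad")) {
  engine <- match.arg(engine)
  ctrl <- utils::modifyList(list(maxit = 500L, rel_tol = 1e-8,
                                 grad_tol = 1e-4), control)
  model <- validate_spec(spec, data)
  start_params <- start %||% start_values(model, data)
  obj <- if (engine == "native") native_objective(model, start_params, M)
  else make_objective(model, start_params, M)
  if (!is.finite(obj$fn(obj$par)))
    stop("log-likelihood is not finite at the starting values")
  opt <- stats::nlminb(obj$par, obj$fn, obj$gr,
                       control = list(rel.tol = ctrl$rel_tol,
                                      iter.max = ctrl$maxit,
                                      eval.max = 10L * ctrl$maxit))
  gr <- as.numeric(obj$gr(opt$par))
  grad_norm <- max(abs(gr))
  converged <- opt$convergence == 0L
  par_free <- stats::setNames(as.numeric(opt$par), model$par_names)
  params <- unpack_parameters(par_free, model)

  vcov <- NULL
  se_ok <- FALSE
  if (se) {
    H <- tryCatch(stats::optimHess(opt$par, obj$fn, obj$gr),
                  error = function(e) NULL)
    if (!is.null(H)) {
      H <- (H + t(H)) / 2
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(is.finite(vc)) && all(diag(vc) > 0)) {
        vcov <- vc
        dimnames(vcov) <- list(model$par_names, model$par_names)
        se_ok <- TRUE
      } else {
        ev <- eigen(H, symmetric = TRUE)
        nn <- length(par_free)
        culprit <- model$par_names[which.max(abs(ev$vectors[, nn]))]
        warning("observed information is not invertible; weakest direction ",
                "loads on '", culprit, "' (eigenvalue ",
                format(ev$values[nn], digits = 3), ")")
        converged <- FALSE
      }
    }
  }

  fit <- structure(list(
    coefficients = NULL,
    params = params,
    par_free = par_free,
    vcov = vcov,
    loglik = -opt$objective,
    converged = converged,
    se_ok = se_ok,
    iterations = opt$iterations,
    grad_norm = grad_norm,
    M = M,
    family = model$family,
    model = model,
    control = ctrl,
    message = opt$message,
    start = start_params), class = "lvcrm_fit")
  fit$coefficients <- parameter_table(fit)
  fit
}

## natural-scale vector of reportable parameters as a function of the free
## vector; used for the coefficient table's delta-method SEs
natural_vector <- function(v, model) {
  pp <- unpack_parameters(v, model)
  out <- c(stats::setNames(pp$beta, paste0("beta_", names(pp$beta))),
           if (model$p) stats::setNames(pp$gamma, paste0("gamma_", names(pp$gamma))),
           if (nrow(model$gi))
             stats::setNames(pp$Gamma[model$gi],
                             paste0("gamma_", model$latents[model$gi[, 1]], ":",
                                    model$latents[model$gi[, 2]])),
           if (nrow(model$om))
             stats::setNames(pp$Omega[model$om],
                             paste0("omega_", model$covariates[model$om[, 2]],
                                    ":", model$latents[model$om[, 1]])),
           if (model$q) stats::setNames(pp$nu, paste0("nu_", model$indicators)),
           if (model$q) stats::setNames(pp$lambda,
                                        paste0("lambda_", model$indicators)),
           if (model$q) stats::setNames(pp$theta,
                                        paste0("theta_", model$indicators)),
           if (model$p) stats::setNames(pp$mu_eta, paste0("mu_", model$latents)),
           if (model$p) stats::setNames(sqrt(diag(pp$Sigma_eta)),
                                        paste0("sd_", model$latents)))
  if (model$p >= 2) {
    R <- stats::cov2cor(pp$Sigma_eta)
    prs <- which(lower.tri(R), arr.ind = TRUE)
    prs <- prs[order(prs[, 1], prs[, 2]), , drop = FALSE]
    out <- c(out, stats::setNames(R[prs],
                                  paste0("cor_", model$latents[prs[, 1]], ".",
                                         model$latents[prs[, 2]])))
  }
  if (!is.null(pp$dispersion))
    out <- c(out, dispersion = unname(pp$dispersion))
  out
}

parameter_table <- function(fit, level = 0.95) {
  model <- fit$model
  est <- natural_vector(fit$par_free, model)
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    se = NA_real_, lower = NA_real_, upper = NA_real_,
                    z = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(fit$vcov)) {
    J <- numDeriv::jacobian(function(v) natural_vector(v, model),
                            fit$par_free)
    Vn <- J %*% fit$vcov %*% t(J)
    tab$se <- sqrt(pmax(diag(Vn), 0))
    zq <- stats::qnorm((1 + level) / 2)
    tab$lower <- tab$estimate - zq * tab$se
    tab$upper <- tab$estimate + zq * tab$se
    tab$z <- tab$estimate / tab$se
    tab$p_value <- 2 * stats::pnorm(-abs(tab$z))
  }
  rownames(tab) <- NULL
  tab
}

#' Wald confidence intervals for fitted parameters
#'
#' `estimate +/- z_(1+level)/2 * SE` on the natural scale.
#'
#' @param fit an `lvcrm_fit` (or `lvcrm_glm`) object.
#' @param level confidence level (default 0.95).
#' @param parameters optional subset of parameter names.
#' @return data frame with estimate, se, lower, upper.
#' @export
wald_ci <- function(fit, level = 0.95, parameters = NULL) {
  tab <- parameter_table(fit, level = level)
  if (!is.null(parameters)) {
    idx <- match(parameters, tab$parameter)
    if (anyNA(idx))
      stop("unknown parameter(s): ",
           paste(parameters[is.na(idx)], collapse = ", "))
    tab <- tab[idx, , drop = FALSE]
  }
  tab[, c("parameter", "estimate", "se", "lower", "upper")]
}

#' @export
coef.lvcrm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  object$coefficients$parameter)
}

#' @export
vcov.lvcrm_fit <- function(object, ...) object$vcov

#' @export
logLik.lvcrm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par_free),
            nobs = object$model$n, class = "logLik")
}

#' @export
confint.lvcrm_fit <- function(object, parm = NULL, level = 0.95, ...) {
  wald_ci(object, level = level, parameters = parm)
}

#' @export
print.lvcrm_fit <- function(x, digits = 4, ...) {
  cat("Latent variable count regression (", x$family, ", log link)\n",
      sep = "")
  cat("Marginal ML, ", x$M, " Gauss-Hermite points per dimension; ",
      "log-likelihood ", format(x$loglik, digits = 8), "\n", sep = "")
  cat(if (x$converged) "Converged" else "NOT converged",
      "in", x$iterations, "iterations; max |gradient| =",
      format(x$grad_norm, digits = 3), "\n\n")
  tab <- x$coefficients
  struct <- grepl("^(beta_|gamma_|omega_|dispersion)", tab$parameter)
  print(format(tab[struct, ], digits = digits), row.names = FALSE)
  cat("... plus", sum(!struct), "measurement/latent parameters",
      "(see $coefficients)\n")
  invisible(x)
}
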