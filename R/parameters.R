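#' Error variance implied by a fixed reliability
#'
#' For a single-indicator latent variable on a unit-variance scale, fixing
#' the indicator's reliability at `Rel` constrains its measurement error
#' variance to \eqn{\lambda^2 (1/\mathrm{Rel} - 1)}. During estimation the
#' constraint is registered so that the error variance tracks the loading
#' (and, under marker scaling, the latent variance) at every iteration.
#'
#' @param loading the factor loading \eqn{\lambda}.
#' @param reliability reliability in (0, 1].
#' @return the constrained error variance.
#' @examples
#' fixed_reliability_error_variance(1, 0.82)  # 0.2195122
#' @export
fixed_reliability_error_variance <- function(loading, reliability) {
  if (any(reliability <= 0 | reliability > 1))
    stop("reliability must lie in (0, 1]")
  loading^2 * (1 / reliability - 1)
}

## names of the free parameter vector, in objective order
free_par_names <- function(model) {
  f <- model$free
  cn <- colnames(model$Z)
  lat <- model$latents
  nm <- c(paste0("beta_", cn),
          if (model$p) paste0("gamma_", lat),
          if (nrow(model$gi))
            paste0("gamma_", lat[model$gi[, 1]], ":", lat[model$gi[, 2]]),
          if (nrow(model$om))
            paste0("omega_", model$covariates[model$om[, 2]], ":",
                   lat[model$om[, 1]]))
  nm <- c(nm,
          paste0("nu_", model$indicators)[f$nu],
          paste0("lambda_", model$indicators)[f$lambda],
          paste0("log_theta_", model$indicators)[f$logtheta],
          paste0("mu_", lat)[f$mu_eta],
          paste0("log_sd_", lat)[f$logsd_eta])
  if (any(f$corr_tr)) {
    prs <- which(lower.tri(diag(model$p)), arr.ind = TRUE)
    prs <- prs[order(prs[, 1], prs[, 2]), , drop = FALSE]
    nm <- c(nm, paste0("corr_tr_", lat[prs[, 1]], ".", lat[prs[, 2]]))
  }
  if (f$logdisp) nm <- c(nm, "log_dispersion")
  nm
}

## a full natural-scale parameter set with every fixed slot at its fixed
## value and free slots at neutral defaults
empty_parameters <- function(model) {
  p <- model$p; q <- model$q; m <- model$m
  lam <- rep(1, q)
  nu <- rep(0, q)
  params <- list(
    beta = stats::setNames(rep(0, m + 1L), colnames(model$Z)),
    gamma = stats::setNames(rep(0, p), model$latents),
    Gamma = matrix(0, p, p, dimnames = list(model$latents, model$latents)),
    Omega = matrix(0, p, m, dimnames = list(model$latents,
                                            model$covariates)),
    nu = stats::setNames(nu, model$indicators),
    lambda = stats::setNames(lam, model$indicators),
    theta = stats::setNames(rep(1, q), model$indicators),
    mu_eta = stats::setNames(rep(0, p), model$latents),
    Sigma_eta = diag(p) + 0,
    dispersion = if (model$family == "negbin") 1 else NULL)
  if (p) dimnames(params$Sigma_eta) <- list(model$latents, model$latents)
  class(params) <- "lvcrm_params"
  params
}

## apply constrained slots (fixed-reliability error variances)
apply_constraints <- function(params, model) {
  if (length(model$rel_idx)) {
    d <- model$load_lat[model$rel_idx]
    veta <- diag(params$Sigma_eta)[d]
    params$theta[model$rel_idx] <-
      fixed_reliability_error_variance(params$lambda[model$rel_idx],
                                       model$rel_val) * veta
  }
  params
}

#' Pack a natural-scale parameter set into the free vector
#'
#' The optimizer works on a flat vector of free parameters: structural
#' coefficients unchanged, error variances and latent SDs on the log scale,
#' the latent correlation factor through a row-normalised unit lower
#' triangle, and the NB dispersion as log(size). Fixed and constrained slots
#' never enter the vector. `pack_parameters()` and [unpack_parameters()] are
#' exact inverses on the free slots.
#'
#' @param params an `lvcrm_params` list (see [unpack_parameters()]).
#' @param model an [validate_spec()] result.
#' @return named numeric vector of free parameters.
#' @export
pack_parameters <- function(params, model) {
  f <- model$free
  gi <- model$gi; om <- model$om
  v <- c(params$beta,
         if (model$p) params$gamma,
         if (nrow(gi)) params$Gamma[gi],
         if (nrow(om)) params$Omega[om],
         params$nu[f$nu],
         params$lambda[f$lambda],
         log(params$theta)[f$logtheta],
         params$mu_eta[f$mu_eta],
         (0.5 * log(diag(params$Sigma_eta)))[f$logsd_eta])
  if (any(f$corr_tr)) {
    R <- stats::cov2cor(params$Sigma_eta)
    v <- c(v, cor_to_tr(R))
  }
  if (f$logdisp) v <- c(v, log(params$dispersion))
  stats::setNames(as.numeric(v), model$par_names)
}

#' Unpack a free parameter vector into natural-scale parameters
#'
#' Inverse of [pack_parameters()]: reconstitutes the full parameter set
#' (structural coefficients `beta`, `gamma`, the strictly upper-triangular
#' interaction matrix `Gamma`, the latent-by-manifest matrix `Omega`,
#' measurement intercepts `nu`, loadings `lambda`, error variances `theta`,
#' latent mean `mu_eta` and covariance `Sigma_eta`, and the NB `dispersion`)
#' with fixed slots at their fixed values and constrained slots recomputed
#' from their drivers (fixed-reliability error variances track the loading).
#'
#' @param v named or unnamed numeric vector of free parameters.
#' @param model an [validate_spec()] result.
#' @return an `lvcrm_params` list.
#' @export
unpack_parameters <- function(v, model) {
  f <- model$free
  params <- empty_parameters(model)
  i <- 0L
  take <- function(k) {
    out <- v[i + seq_len(k)]
    i <<- i + k
    out
  }
  params$beta[] <- take(model$m + 1L)
  if (model$p) params$gamma[] <- take(model$p)
  if (nrow(model$gi)) params$Gamma[model$gi] <- take(nrow(model$gi))
  if (nrow(model$om)) params$Omega[model$om] <- take(nrow(model$om))
  if (model$scaling == "marker" && model$p) {
    first <- match(seq_len(model$p), model$load_lat)
    params$lambda[first] <- 1
    params$nu[first] <- 0
  }
  params$nu[f$nu] <- take(sum(f$nu))
  params$lambda[f$lambda] <- take(sum(f$lambda))
  params$theta[f$logtheta] <- exp(take(sum(f$logtheta)))
  params$mu_eta[f$mu_eta] <- take(sum(f$mu_eta))
  sd_eta <- rep(1, model$p)
  sd_eta[f$logsd_eta] <- exp(take(sum(f$logsd_eta)))
  R <- if (any(f$corr_tr))
    tr_to_cor(take(sum(f$corr_tr)), model$p) else diag(model$p)
  if (model$p) {
    params$Sigma_eta <- diag(sd_eta, model$p) %*% R %*% diag(sd_eta, model$p)
    dimnames(params$Sigma_eta) <- list(model$latents, model$latents)
  }
  if (f$logdisp) params$dispersion <- unname(exp(take(1L)))
  if (i != length(v))
    stop("parameter vector has length ", length(v), ", expected ", i)
  apply_constraints(params, model)
}

#' @export
print.lvcrm_params <- function(x, ...) {
  cat("LV-CRM parameter set\n")
  cat("  beta:  ", paste(sprintf("%s=%.3f", names(x$beta), x$beta),
                         collapse = ", "), "\n")
  if (length(x$gamma))
    cat("  gamma: ", paste(sprintf("%s=%.3f", names(x$gamma), x$gamma),
                           collapse = ", "), "\n")
  if (!is.null(x$dispersion))
    cat("  dispersion:", format(x$dispersion, digits = 4), "\n")
  invisible(x)
}
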