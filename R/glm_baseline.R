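#' Sum scores of the latent-variable indicators
#'
#' Row sums of each latent variable's indicators, z-standardized with the
#' sample mean and sample SD (denominator `n - 1`) for comparability with
#' standardized latent variables. These fallible scores are the covariates
#' of the GLM comparison estimator.
#'
#' @param data data frame with the indicator columns.
#' @param spec an [lvcrm_spec()] (supplies the indicator-to-latent map),
#'   or a named list latent -> indicator columns.
#' @return data frame of class `lvcrm_sumscores` with columns
#'   `<latent>_raw` and `<latent>` (standardized); standardization constants
#'   are kept in `attr(, "center")` / `attr(, "scale")`.
#' @export
sum_scores <- function(data, spec) {
  grouping <- if (inherits(spec, "lvcrm_spec")) spec$measurement else spec
  if (!length(grouping)) stop("no latent variables / indicator groups")
  out <- data.frame(row.names = seq_len(nrow(data)))
  center <- scale_ <- stats::setNames(numeric(length(grouping)),
                                      names(grouping))
  for (l in names(grouping)) {
    cols <- grouping[[l]]
    if (!length(cols)) stop("empty indicator group for '", l, "'")
    missing_cols <- setdiff(cols, names(data))
    if (length(missing_cols))
      stop("indicator columns not in data: ",
           paste(missing_cols, collapse = ", "))
    raw <- rowSums(data[, cols, drop = FALSE])
    s <- stats::sd(raw)
    if (!is.finite(s) || s == 0)
      stop("sum score for '", l, "' has zero variance")
    out[[paste0(l, "_raw")]] <- raw
    out[[l]] <- (raw - mean(raw)) / s
    center[l] <- mean(raw)
    scale_[l] <- s
  }
  attr(out, "center") <- center
  attr(out, "scale") <- scale_
  class(out) <- c("lvcrm_sumscores", class(out))
  out
}

#' Sum-score GLM comparison estimator
#'
#' Fits the count GLM that a researcher ignoring measurement error would
#' use: the latent variables are replaced by their z-standardized sum
#' scores, product terms are formed from the standardized scores
#' (standardize-then-multiply), and the model is estimated by IRLS
#' ([stats::glm()], Poisson) or by alternating IRLS with ML estimation of
#' the dispersion ([MASS::glm.nb()], NB2). Structural coefficients are
#' reported under the same names as in [lvcrm_fit()] so that the two
#' estimators can be compared parameter by parameter.
#'
#' @param data data frame with outcome, covariate and indicator columns.
#' @param spec an [lvcrm_spec()].
#' @return an object of class `lvcrm_glm` with a `$coefficients` table,
#'   `$glm` (the underlying fit), `$vcov`, `$loglik`, `$converged`.
#' @export
glm_baseline <- function(data, spec) {
  stopifnot(inherits(spec, "lvcrm_spec"))
  if (!spec$outcome %in% names(data))
    stop("outcome '", spec$outcome, "' not in data")
  latents <- names(spec$measurement)
  df <- data.frame(.y = data[[spec$outcome]], check.names = FALSE)
  for (cv in spec$covariates) df[[cv]] <- data[[cv]]
  scores <- NULL
  if (length(latents)) {
    scores <- sum_scores(data, spec)
    for (l in latents) df[[l]] <- scores[[l]]
  }
  terms <- c(spec$covariates, latents,
             vapply(spec$interactions, paste, "", collapse = ":"),
             vapply(spec$latent_covariate_interactions,
                    function(pr) paste(pr[2], pr[1], sep = ":"), ""))
  fml <- stats::as.formula(paste(".y ~",
                                 if (length(terms))
                                   paste(terms, collapse = " + ") else "1"))
  fit0 <- if (spec$family == "poisson") {
    stats::glm(fml, family = stats::poisson(), data = df)
  } else {
    suppressWarnings(MASS::glm.nb(fml, data = df))
  }
  if (any(is.na(stats::coef(fit0))))
    stop("rank-deficient design in the GLM baseline")

  ## rename coefficients to the lvcrm convention
  cf <- stats::coef(fit0)
  vc <- stats::vcov(fit0)
  nm <- names(cf)
  rename <- function(nm) {
    out <- nm
    out[nm == "(Intercept)"] <- "beta_(Intercept)"
    out[nm %in% spec$covariates] <- paste0("beta_", nm[nm %in% spec$covariates])
    out[nm %in% latents] <- paste0("gamma_", nm[nm %in% latents])
    for (pr in spec$interactions) {
      hit <- nm %in% c(paste(pr, collapse = ":"),
                       paste(rev(pr), collapse = ":"))
      out[hit] <- paste0("gamma_", pr[1], ":", pr[2])
    }
    for (pr in spec$latent_covariate_interactions) {
      hit <- nm %in% c(paste(pr[2], pr[1], sep = ":"),
                       paste(pr[1], pr[2], sep = ":"))
      out[hit] <- paste0("omega_", pr[2], ":", pr[1])
    }
    out
  }
  names(cf) <- rename(nm)
  dimnames(vc) <- list(names(cf), names(cf))
  est <- cf
  se <- sqrt(diag(vc))
  if (spec$family == "negbin") {
    est <- c(est, dispersion = unname(fit0$theta))
    se <- c(se, dispersion = unname(fit0$SE.theta))
  }
  zq <- stats::qnorm(0.975)
  tab <- data.frame(parameter = names(est), estimate = unname(est),
                    se = unname(se), lower = unname(est - zq * se),
                    upper = unname(est + zq * se),
                    z = unname(est / se),
                    p_value = unname(2 * stats::pnorm(-abs(est / se))),
                    stringsAsFactors = FALSE)
  structure(list(coefficients = tab, glm = fit0, vcov = vc,
                 loglik = as.numeric(stats::logLik(fit0)),
                 converged = fit0$converged %||% TRUE,
                 family = spec$family, spec = spec,
                 scores = scores,
                 z_means = if (length(spec$covariates))
                   colMeans(df[, spec$covariates, drop = FALSE])
                 else numeric(0)),
            class = "lvcrm_glm")
}

#' @export
coef.lvcrm_glm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  object$coefficients$parameter)
}

#' @export
vcov.lvcrm_glm <- function(object, ...) object$vcov

#' @export
logLik.lvcrm_glm <- function(object, ...) stats::logLik(object$glm)

#' @export
print.lvcrm_glm <- function(x, digits = 4, ...) {
  cat("Sum-score GLM baseline (", x$family, ", log link)\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}
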