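#' Specify a latent variable count regression model
#'
#' Declares the measurement model (which indicator columns load on which
#' latent variable; congeneric structure, i.e. each indicator loads on
#' exactly one latent), the structural part of the linear predictor
#' (manifest covariates, latent main effects, latent-by-latent and
#' latent-by-manifest product terms), the outcome family and the scaling
#' convention that identifies the factor model.
#'
#' The linear predictor is
#' \deqn{\pi_i = z_i\beta + \gamma'\eta_i + \eta_i'\Gamma\eta_i +
#'   \eta_i'\Omega z_i}
#' with \eqn{\Gamma} strictly upper triangular (no latent squares) and the
#' outcome mean \eqn{\mu_i = \exp(\pi_i)}; the indicators follow
#' \eqn{w_i = \nu + \Lambda\eta_i + \epsilon_i} with diagonal error
#' covariance \eqn{\Theta} and \eqn{\eta_i \sim N(\mu_\eta, \Sigma_\eta)}.
#'
#' @param outcome name of the count outcome column.
#' @param measurement named list; names are latent-variable names, each
#'   element a character vector of indicator column names. May be empty
#'   (a plain GLM, no latent variables).
#' @param covariates character vector of manifest covariate columns
#'   (an intercept is always included).
#' @param interactions list of length-2 character vectors naming latent
#'   pairs with a product term, or `"all"` for every pair. Order within a
#'   pair is irrelevant; latent squares are not allowed.
#' @param latent_covariate_interactions list of length-2 character vectors
#'   `c(latent, covariate)` with a latent-by-manifest product term.
#' @param family `"poisson"` or `"negbin"` (NB2: Var = mu + mu^2/theta).
#' @param scaling `"standardized"` (latent means fixed to 0, variances to 1;
#'   all loadings and intercepts free) or `"marker"` (first loading fixed to
#'   1 and first intercept to 0 per latent; latent means and variances free).
#'   Latent correlations are freely estimated under both conventions.
#' @param fixed_reliability named numeric vector; names are indicator
#'   columns whose error variance is constrained to
#'   \eqn{\lambda^2 \mathrm{Var}(\eta)(1/\mathrm{Rel} - 1)} so that the
#'   indicator's reliability is fixed at the given value. This is how a
#'   single-indicator latent variable is identified.
#' @return an object of class `lvcrm_spec`.
#' @seealso [validate_spec()], [lvcrm_fit()], [glm_baseline()]
#' @examples
#' spec <- lvcrm_spec(
#'   outcome = "y",
#'   measurement = list(eta1 = c("w1", "w2", "w3"),
#'                      eta2 = c("w4", "w5", "w6")),
#'   interactions = "all", family = "poisson")
#' @export
lvcrm_spec <- function(outcome,
                       measurement = list(),
                       covariates = character(),
                       interactions = NULL,
                       latent_covariate_interactions = NULL,
                       family = c("poisson", "negbin"),
                       scaling = c("standardized", "marker"),
                       fixed_reliability = NULL) {
  family <- match.arg(family)
  scaling <- match.arg(scaling)
  stopifnot(is.character(outcome), length(outcome) == 1L)
  if (length(measurement)) {
    if (is.null(names(measurement)) || any(names(measurement) == ""))
      stop("'measurement' must be a named list (latent -> indicators)")
    ind <- unlist(measurement, use.names = FALSE)
    if (anyDuplicated(ind))
      stop("each indicator may load on exactly one latent variable ",
           "(congeneric structure); duplicated: ",
           paste(ind[duplicated(ind)], collapse = ", "))
  }
  latents <- names(measurement)
  if (identical(interactions, "all")) {
    interactions <- if (length(latents) >= 2)
      utils::combn(latents, 2, simplify = FALSE) else list()
  }
  interactions <- lapply(interactions %||% list(), function(pr) {
    pr <- as.character(pr)
    if (length(pr) != 2L || pr[1] == pr[2])
      stop("latent interactions must name two distinct latent variables")
    if (!all(pr %in% latents))
      stop("unknown latent variable in interaction: ",
           paste(setdiff(pr, latents), collapse = ", "))
    pr[order(match(pr, latents))]
  })
  lci <- lapply(latent_covariate_interactions %||% list(), function(pr) {
    pr <- as.character(pr)
    if (length(pr) != 2L)
      stop("latent-covariate interactions must be c(latent, covariate)")
    if (!pr[1] %in% latents)
      stop("unknown latent variable: ", pr[1])
    if (!pr[2] %in% covariates)
      stop("unknown covariate: ", pr[2])
    pr
  })
  if (!is.null(fixed_reliability)) {
    if (is.null(names(fixed_reliability)))
      stop("'fixed_reliability' must be a named vector (indicator = value)")
    if (any(fixed_reliability <= 0 | fixed_reliability > 1))
      stop("reliabilities must lie in (0, 1]")
    bad <- setdiff(names(fixed_reliability),
                   unlist(measurement, use.names = FALSE))
    if (length(bad))
      stop("fixed_reliability names are not indicators: ",
           paste(bad, collapse = ", "))
  }
  structure(list(outcome = outcome,
                 measurement = measurement,
                 covariates = as.character(covariates),
                 interactions = interactions,
                 latent_covariate_interactions = lci,
                 family = family,
                 scaling = scaling,
                 fixed_reliability = fixed_reliability),
            class = "lvcrm_spec")
}

#' Switch the scaling (identification) convention of a specification
#'
#' Under `"marker"` scaling the first loading of every latent is fixed to 1
#' and the first intercept to 0, while the latent means and variances are
#' free; under `"standardized"` scaling the latent means are fixed to 0 and
#' the variances to 1, while all loadings and intercepts are free. The two
#' conventions identify equivalent models: the maximized log-likelihoods
#' coincide and the estimates map onto each other by rescaling with the
#' latent standard deviations.
#'
#' @param spec an [lvcrm_spec()] object.
#' @param scaling `"standardized"` or `"marker"`.
#' @return the specification with the scaling replaced.
#' @export
apply_scaling <- function(spec, scaling = c("standardized", "marker")) {
  stopifnot(inherits(spec, "lvcrm_spec"))
  spec$scaling <- match.arg(scaling)
  spec
}

#' @export
print.lvcrm_spec <- function(x, ...) {
  cat("Latent variable count regression specification\n")
  cat("  outcome:    ", x$outcome, " (", x$family, ", log link)\n", sep = "")
  cat("  covariates: ",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n", sep = "")
  for (l in names(x$measurement))
    cat("  latent ", l, ": ", paste(x$measurement[[l]], collapse = ", "),
        "\n", sep = "")
  if (length(x$interactions))
    cat("  latent interactions: ",
        paste(vapply(x$interactions, paste, "", collapse = ":"),
              collapse = ", "), "\n", sep = "")
  if (length(x$latent_covariate_interactions))
    cat("  latent-covariate interactions: ",
        paste(vapply(x$latent_covariate_interactions, paste, "",
                     collapse = ":"), collapse = ", "), "\n", sep = "")
  cat("  scaling:    ", x$scaling, "\n", sep = "")
  if (!is.null(x$fixed_reliability))
    cat("  fixed reliabilities: ",
        paste(names(x$fixed_reliability), "=", x$fixed_reliability,
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Resolve and validate a model against a dataset
#'
#' Checks that every referenced column exists, that the outcome is a
#' non-negative integer count, applies the scaling convention, enumerates
#' all parameter slots (free, fixed, constrained) and runs counting-rule
#' identification checks on every measurement block.
#'
#' A block with a single indicator is identified only if at most one of its
#' loading / error-variance / latent-variance slots remains free -- e.g.
#' through a fixed-reliability constraint. Two-indicator blocks borrow
#' information through the free latent covariance and are accepted only when
#' another latent variable is present.
#'
#' @param spec an [lvcrm_spec()].
#' @param data a data frame containing all referenced columns.
#' @return an object of class `lvcrm_model` with resolved dimensions
#'   (`n`, `m`, `p`, `q`), index maps, free/fixed masks and the design
#'   matrices.
#' @export
validate_spec <- function(spec, data) {
  stopifnot(inherits(spec, "lvcrm_spec"), is.data.frame(data))
  needed <- c(spec$outcome, spec$covariates,
              unlist(spec$measurement, use.names = FALSE))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))

  y <- data[[spec$outcome]]
  if (any(is.na(y)) || any(y < 0) || any(y != round(y)))
    stop("outcome '", spec$outcome,
         "' must be a non-negative integer count; offending rows: ",
         paste(utils::head(which(is.na(y) | y < 0 | y != round(y)), 5),
               collapse = ", "))

  latents <- names(spec$measurement)
  indicators <- unlist(spec$measurement, use.names = FALSE)
  p <- length(latents)
  q <- length(indicators)
  m <- length(spec$covariates)
  n <- nrow(data)
  load_lat <- rep(seq_len(p), times = lengths(spec$measurement))

  Z <- if (m) {
    cbind(`(Intercept)` = 1, as.matrix(data[, spec$covariates, drop = FALSE]))
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  W <- if (q) as.matrix(data[, indicators, drop = FALSE]) else
    matrix(0, n, 0)
  if (q && any(is.na(W)))
    stop("missing values in indicator columns; apply read_lvcrm_data() ",
         "or complete cases first")
  if (m && any(is.na(Z)))
    stop("missing values in covariate columns")

  gi <- if (length(spec$interactions))
    t(vapply(spec$interactions, function(pr) match(pr, latents),
             integer(2))) else matrix(integer(0), 0, 2)
  om <- if (length(spec$latent_covariate_interactions))
    t(vapply(spec$latent_covariate_interactions,
             function(pr) c(match(pr[1], latents),
                            match(pr[2], spec$covariates)),
             integer(2))) else matrix(integer(0), 0, 2)

  ## reliability constraints
  rel_idx <- integer(0); rel_val <- numeric(0)
  if (!is.null(spec$fixed_reliability)) {
    rel_idx <- match(names(spec$fixed_reliability), indicators)
    rel_val <- unname(spec$fixed_reliability)
  }

  ## free/fixed masks per block, following the scaling convention
  free <- list(beta = rep(TRUE, m + 1L),
               gamma = rep(TRUE, p),
               gammaI = rep(TRUE, nrow(gi)),
               omega = rep(TRUE, nrow(om)),
               nu = rep(TRUE, q),
               lambda = rep(TRUE, q),
               logtheta = rep(TRUE, q),
               mu_eta = rep(TRUE, p),
               logsd_eta = rep(TRUE, p),
               corr_tr = rep(TRUE, if (p >= 2) p * (p - 1L) / 2L else 0L),
               logdisp = spec$family == "negbin")
  if (p) {
    if (spec$scaling == "standardized") {
      free$mu_eta[] <- FALSE
      free$logsd_eta[] <- FALSE
    } else {
      first <- match(seq_len(p), load_lat)
      free$lambda[first] <- FALSE
      free$nu[first] <- FALSE
    }
  }
  if (length(rel_idx)) free$logtheta[rel_idx] <- FALSE

  ## identification counting rules per measurement block
  for (d in seq_len(p)) {
    blk <- which(load_lat == d)
    k <- length(blk)
    nfree_meas <- sum(free$lambda[blk]) + sum(free$logtheta[blk]) +
      free$logsd_eta[d]
    if (k == 1L && nfree_meas > 1L)
      stop("latent variable '", latents[d], "' is not identified: a single ",
           "indicator cannot identify ", nfree_meas, " free measurement ",
           "parameters; fix the loading, the error variance or use a ",
           "fixed-reliability constraint")
    if (k == 2L && p < 2L)
      stop("latent variable '", latents[d], "' is not identified: ",
           "two indicators identify a lone factor only with additional ",
           "constraints")
    if (nfree_meas > k * (k + 1L) / 2L)
      stop("latent variable '", latents[d], "' is not identified: ",
           nfree_meas, " free measurement parameters exceed the ",
           k * (k + 1L) / 2L, " within-block (co)variances")
  }

  model <- structure(list(
    spec = spec, n = n, m = m, p = p, q = q,
    outcome = spec$outcome, covariates = spec$covariates,
    latents = latents, indicators = indicators,
    load_lat = load_lat, gi = gi, om = om,
    rel_idx = rel_idx, rel_val = rel_val,
    family = spec$family, scaling = spec$scaling,
    free = free,
    y = as.numeric(y), Z = Z, W = W,
    z_means = if (m) colMeans(Z[, -1L, drop = FALSE]) else numeric(0)),
    class = "lvcrm_model")
  model$par_names <- free_par_names(model)
  model
}

#' @export
print.lvcrm_model <- function(x, ...) {
  cat("Validated LV-CRM model: n =", x$n, ", m =", x$m, "covariates, p =",
      x$p, "latent variables, q =", x$q, "indicators\n")
  cat("Free parameters:", length(x$par_names), "\n")
  invisible(x)
}
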