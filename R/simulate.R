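#' Indicator error variance implied by a target sum-score reliability
#'
#' For a latent variable with unit variance measured by `k` congeneric
#' indicators with loadings `loadings`, the sum score has reliability
#' \eqn{(\sum\lambda)^2 / [(\sum\lambda)^2 + k\theta]} when every indicator
#' has the same error variance \eqn{\theta}. Solving for \eqn{\theta} gives
#' \deqn{\theta = (\sum\lambda)^2 (1 - \mathrm{rel}) / (k\,\mathrm{rel})}
#' which is how the generators manipulate reliability.
#'
#' @param rel target sum-score reliability in (0, 1].
#' @param loadings vector of factor loadings (length `k`).
#' @return the common per-indicator error variance.
#' @examples
#' reliability_to_error_variance(0.7, c(1, 1, 1))  # 1.285714
#' @export
reliability_to_error_variance <- function(rel, loadings) {
  if (rel <= 0 || rel > 1) stop("'rel' must lie in (0, 1]")
  k <- length(loadings)
  sum(loadings)^2 * (1 - rel) / (k * rel)
}

study3_pattern <- function(x, what) {
  ## (a) all -0.3, (b) all +0.3, (c) all 0, (d) mixed (-0.3, 0.3, 0)
  if (is.character(x)) {
    x <- match.arg(x, c("negative", "positive", "zero", "mixed"))
    switch(x, negative = rep(-0.3, 3), positive = rep(0.3, 3),
           zero = rep(0, 3), mixed = c(-0.3, 0.3, 0))
  } else {
    if (length(x) != 3) stop("'", what, "' needs 3 values (12, 13, 23)")
    as.numeric(x)
  }
}

#' Monte-Carlo simulation design
#'
#' Assembles the data-generating process of one of the three built-in
#' study families (or a custom variant) together with the analysis
#' specification both estimators use:
#'
#' * `study = 1`: Poisson outcome, two standard-normal latent predictors
#'   (correlation 0.3), three unit-loading indicators each, linear
#'   predictor `0.2 + 0.3*eta1 + 0.3*eta2 + gamma_int*eta1*eta2`.
#' * `study = 2`: as study 1 plus three independent, perfectly reliable
#'   N(0, 1) manifest covariates with coefficients 0.2, and an NB2 outcome
#'   with dispersion 2.
#' * `study = 3`: Poisson outcome, three latent predictors with all three
#'   pairwise product terms; correlation and interaction patterns
#'   `"negative"`, `"positive"`, `"zero"`, `"mixed"` (`-0.3, 0.3, 0`).
#'
#' Reliability of each latent's sum score is controlled through the
#' indicator error variances ([reliability_to_error_variance()]).
#'
#' @param study 1, 2 or 3.
#' @param n sample size per replication.
#' @param reliabilities per-latent sum-score reliabilities.
#' @param gamma_int product-term coefficient(s): a scalar for studies 1-2,
#'   three values (or a pattern name) for study 3.
#' @param latent_cor latent correlation(s): a scalar for studies 1-2
#'   (default 0.3), three values or a pattern name for study 3.
#' @param beta0 structural intercept (default 0.2).
#' @param gamma_main latent main effects (default 0.3 each).
#' @param beta_x study-2 manifest coefficients (default 0.2 each).
#' @param family overrides the study default family.
#' @param dispersion NB2 size parameter (study 2 default 2).
#' @param indicators_per_latent indicators per latent (default 3; a value
#'   of 1 generates a single-indicator latent to be fitted with a
#'   fixed-reliability constraint).
#' @return an object of class `lvcrm_design`; `$spec` holds the matching
#'   [lvcrm_spec()] (standardized-latent scaling, free latent correlation).
#' @export
sim_design <- function(study = 1, n = 500,
                       reliabilities = c(0.8, 0.8),
                       gamma_int = 0.3,
                       latent_cor = NULL,
                       beta0 = 0.2, gamma_main = 0.3, beta_x = 0.2,
                       family = NULL, dispersion = 2,
                       indicators_per_latent = 3) {
  stopifnot(study %in% 1:3)
  p <- if (study == 3) 3L else 2L
  if (length(reliabilities) == 1L) reliabilities <- rep(reliabilities, p)
  if (length(reliabilities) != p)
    stop("need ", p, " reliabilities")
  if (study == 3) {
    gamma_int <- study3_pattern(gamma_int, "gamma_int")
    latent_cor <- study3_pattern(latent_cor %||% "positive", "latent_cor")
  } else {
    stopifnot(length(gamma_int) == 1L)
    latent_cor <- latent_cor %||% 0.3
  }
  family <- family %||% if (study == 2) "negbin" else "poisson"
  k <- indicators_per_latent
  latents <- paste0("eta", seq_len(p))
  R <- diag(p)
  if (p == 2) {
    R[1, 2] <- R[2, 1] <- latent_cor
  } else {
    R[1, 2] <- R[2, 1] <- latent_cor[1]
    R[1, 3] <- R[3, 1] <- latent_cor[2]
    R[2, 3] <- R[3, 2] <- latent_cor[3]
  }
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("latent correlation matrix is not positive definite")
  gamma_main <- rep(gamma_main, length.out = p)
  covs <- if (study == 2) c("x1", "x2", "x3") else character(0)
  beta_x <- if (study == 2) rep(beta_x, length.out = 3) else numeric(0)
  pairs <- utils::combn(p, 2)
  Gamma <- matrix(0, p, p)
  gi_vals <- if (p == 2) gamma_int else gamma_int
  for (idx in seq_len(ncol(pairs)))
    Gamma[pairs[1, idx], pairs[2, idx]] <- gi_vals[idx]
  theta <- vapply(reliabilities,
                  reliability_to_error_variance, 0, loadings = rep(1, k))
  measurement <- stats::setNames(
    lapply(seq_len(p), function(d) paste0("w", d, "_", seq_len(k))),
    latents)
  int_pairs <- lapply(seq_len(ncol(pairs)),
                      function(idx) latents[pairs[, idx]])
  ## product terms with a true coefficient of zero are still estimated
  spec <- lvcrm_spec(outcome = "y", measurement = measurement,
                     covariates = covs, interactions = int_pairs,
                     family = family, scaling = "standardized")
  structure(list(study = study, n = n, p = p, k = k,
                 reliabilities = reliabilities, latent_cor = R,
                 beta0 = beta0, gamma_main = gamma_main,
                 Gamma = Gamma, beta_x = beta_x,
                 family = family,
                 dispersion = if (family == "negbin") dispersion else NULL,
                 theta = theta, latents = latents, covariates = covs,
                 spec = spec), class = "lvcrm_design")
}

#' @export
print.lvcrm_design <- function(x, ...) {
  cat("Simulation design (study ", x$study, "): n = ", x$n, ", ", x$p,
      " latent variable(s), family = ", x$family, "\n", sep = "")
  cat("  reliabilities:", paste(x$reliabilities, collapse = ", "), "\n")
  cat("  product coefficients:",
      paste(x$Gamma[upper.tri(x$Gamma)], collapse = ", "), "\n")
  invisible(x)
}

#' Generate one dataset from a simulation design
#'
#' Draws latent variables from `N(0, R)`, indicators from the congeneric
#' measurement model with unit loadings, zero intercepts and error
#' variances set by the design reliabilities, manifest covariates (study 2)
#' as independent N(0, 1), and the count outcome from the Poisson or NB2
#' family with log mean equal to the design's linear predictor.
#' Deterministic given `seed`.
#'
#' @param design an [sim_design()].
#' @param seed integer seed.
#' @return data frame with `y`, covariates and indicator columns; the true
#'   parameter values and latent draws are attached as `attr(, "truth")`.
#' @export
simulate_lvcrm <- function(design, seed) {
  stopifnot(inherits(design, "lvcrm_design"))
  set.seed(seed)
  n <- design$n; p <- design$p; k <- design$k
  eta <- matrix(stats::rnorm(n * p), n, p) %*% chol(design$latent_cor)
  W <- matrix(0, n, p * k)
  colnames(W) <- unlist(design$spec$measurement, use.names = FALSE)
  for (d in seq_len(p)) {
    cols <- (d - 1L) * k + seq_len(k)
    W[, cols] <- eta[, d] +
      matrix(stats::rnorm(n * k, sd = sqrt(design$theta[d])), n, k)
  }
  X <- NULL
  pi <- design$beta0 + drop(eta %*% design$gamma_main) +
    rowSums((eta %*% design$Gamma) * eta)
  if (length(design$covariates)) {
    X <- matrix(stats::rnorm(n * length(design$covariates)), n,
                dimnames = list(NULL, design$covariates))
    pi <- pi + drop(X %*% design$beta_x)
  }
  y <- if (design$family == "poisson") stats::rpois(n, exp(pi))
  else stats::rnbinom(n, size = design$dispersion, mu = exp(pi))
  out <- data.frame(y = y)
  if (!is.null(X)) out <- cbind(out, as.data.frame(X))
  out <- cbind(out, as.data.frame(W))
  attr(out, "truth") <- list(eta = eta, pi = pi,
                             params = true_parameters(design))
  out
}

#' True structural parameter values of a design
#'
#' Named vector (lvcrm naming convention) of the data-generating structural
#' coefficients, used by the Monte-Carlo metrics.
#'
#' @param design an [sim_design()].
#' @return named numeric vector.
#' @export
true_parameters <- function(design) {
  lat <- design$latents
  pairs <- utils::combn(design$p, 2)
  c(stats::setNames(design$beta0, "beta_(Intercept)"),
    if (length(design$covariates))
      stats::setNames(design$beta_x, paste0("beta_", design$covariates)),
    stats::setNames(design$gamma_main, paste0("gamma_", lat)),
    stats::setNames(design$Gamma[t(pairs)],
                    paste0("gamma_", lat[pairs[1, ]], ":", lat[pairs[2, ]])))
}

#' Run a seeded Monte-Carlo comparison of the two estimators
#'
#' For each replication: generate a dataset ([simulate_lvcrm()]), fit the
#' sum-score GLM baseline and/or the LV-CRM, and record the structural
#' estimates (optionally with SEs and Wald CIs). A replication in which a
#' requested estimator fails to converge is redrawn with a fresh derived
#' seed (up to `max_redraw` times, then flagged), so the aggregate metrics
#' are computed over converged solutions. Identical base seeds give
#' identical results.
#'
#' @param design an [sim_design()].
#' @param R number of replications.
#' @param seed base seed; per-replication seeds derive from it
#'   ([derive_seed()]).
#' @param estimators subset of `c("glm", "lvcrm")`.
#' @param M quadrature points per dimension for the LV-CRM fits
#'   (default 9; [lvcrm_fit()] itself defaults to 15 -- the engine trades a
#'   little grid resolution for the replication count).
#' @param se record SEs/CIs (needed for coverage and detection metrics);
#'   the GLM baseline always has them.
#' @param resample redraw non-converged replications (default `TRUE`).
#' @param max_redraw redraw cap per replication.
#' @return object of class `lvcrm_sim`: `$estimates` (long data frame, one
#'   row per replication x estimator x parameter), `$truth`, `$design`,
#'   `$n_redrawn`, `$failed`. Summarize with [sim_metrics()].
#' @export
run_simulation <- function(design, R, seed, estimators = c("glm", "lvcrm"),
                           M = 9, se = FALSE, resample = TRUE,
                           max_redraw = 10L) {
  estimators <- match.arg(estimators, c("glm", "lvcrm"),
                          several.ok = TRUE)
  truth <- true_parameters(design)
  keep <- names(truth)
  rows <- vector("list", R * length(estimators))
  n_redrawn <- 0L
  failed <- integer(0)
  for (r in seq_len(R)) {
    redraw <- 0L
    repeat {
      res <- fit_once(design, derive_seed(seed, r, redraw), estimators,
                      keep, M = M, se = se)
      if (res$ok || !resample || redraw >= max_redraw) break
      redraw <- redraw + 1L
      n_redrawn <- n_redrawn + 1L
    }
    if (!res$ok) failed <- c(failed, r)
    for (j in seq_along(estimators)) {
      res$tabs[[j]]$rep <- r
      rows[[(r - 1L) * length(estimators) + j]] <- res$tabs[[j]]
    }
  }
  est <- do.call(rbind, rows)
  structure(list(estimates = est, truth = truth, design = design,
                 R = R, seed = seed, estimators = estimators, M = M,
                 se = se, n_redrawn = n_redrawn, failed = failed),
            class = "lvcrm_sim")
}

fit_once <- function(design, seed_r, estimators, keep, M, se) {
  d <- simulate_lvcrm(design, seed_r)
  tabs <- list()
  ok <- TRUE
  for (e in estimators) {
    tab <- tryCatch({
      if (e == "glm") {
        f <- glm_baseline(d, design$spec)
        conv <- isTRUE(f$converged)
      } else {
        f <- suppressWarnings(lvcrm_fit(d, design$spec, M = M, se = se))
        conv <- f$converged && (!se || f$se_ok)
      }
      cf <- f$coefficients
      cf <- cf[match(keep, cf$parameter), ]
      data.frame(estimator = e, parameter = keep,
                 estimate = cf$estimate, se = cf$se,
                 lower = cf$lower, upper = cf$upper,
                 converged = conv, seed = seed_r,
                 stringsAsFactors = FALSE)
    }, error = function(err) {
      data.frame(estimator = e, parameter = keep, estimate = NA_real_,
                 se = NA_real_, lower = NA_real_, upper = NA_real_,
                 converged = FALSE, seed = seed_r,
                 stringsAsFactors = FALSE)
    })
    ok <- ok && all(tab$converged)
    tabs[[length(tabs) + 1L]] <- tab
  }
  list(tabs = tabs, ok = ok)
}

#' Spill-over statistic
#'
#' Euclidean norm of a vector of coefficient biases; used to summarize how
#' much bias "spills over" from the fallible scores onto the coefficients
#' of perfectly reliable covariates.
#'
#' @param biases numeric vector of biases.
#' @return `sqrt(sum(biases^2))`.
#' @examples
#' spillover(c(0.003, 0.004, 0))  # 0.005
#' @export
spillover <- function(biases) sqrt(sum(biases^2))

#' Monte-Carlo performance metrics
#'
#' Per estimator and parameter: bias (`mean(est) - true`), relative bias in
#' percent (`100 * bias / true`, only for non-zero truths), RMSE
#' (`sqrt(mean((est - true)^2))`), coverage (share of CIs containing the
#' truth) and detection rate (share of CIs excluding zero); plus, when both
#' estimators are present, the relative efficiency `RMSE_lvcrm / RMSE_glm`,
#' and the spill-over statistic `S` over the manifest-covariate biases.
#'
#' @param sim an `lvcrm_sim` from [run_simulation()].
#' @return data frame of metrics (one row per estimator x parameter),
#'   with `attr(, "spillover")` and `attr(, "rel_efficiency")`.
#' @export
sim_metrics <- function(sim) {
  stopifnot(inherits(sim, "lvcrm_sim"))
  est <- sim$estimates
  est <- est[est$converged & is.finite(est$estimate), ]
  truth <- sim$truth
  out <- do.call(rbind, lapply(split(est, est[c("parameter", "estimator")]),
                               function(g) {
    if (!nrow(g)) return(NULL)
    tr <- truth[[g$parameter[1]]]
    bias <- mean(g$estimate) - tr
    data.frame(estimator = g$estimator[1], parameter = g$parameter[1],
               true = tr, mean = mean(g$estimate), bias = bias,
               rel_bias = if (tr != 0) 100 * bias / tr else NA_real_,
               rmse = sqrt(mean((g$estimate - tr)^2)),
               coverage = if (all(is.finite(g$lower)))
                 mean(g$lower <= tr & tr <= g$upper) else NA_real_,
               detection = if (all(is.finite(g$lower)))
                 mean(g$lower > 0 | g$upper < 0) else NA_real_,
               n_rep = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  ## spill-over over manifest covariate biases, per estimator
  sp <- vapply(unique(out$estimator), function(e) {
    b <- out$bias[out$estimator == e &
                    grepl("^beta_x", out$parameter)]
    if (length(b)) spillover(b) else NA_real_
  }, 0)
  attr(out, "spillover") <- sp
  if (all(c("glm", "lvcrm") %in% out$estimator)) {
    ip <- grep(":", out$parameter, fixed = TRUE, value = TRUE)
    re <- vapply(unique(ip), function(pp) {
      out$rmse[out$estimator == "lvcrm" & out$parameter == pp] /
        out$rmse[out$estimator == "glm" & out$parameter == pp]
    }, 0)
    attr(out, "rel_efficiency") <- re
  }
  out
}

#' @export
print.lvcrm_sim <- function(x, ...) {
  cat("Monte-Carlo run: study ", x$design$study, ", R = ", x$R,
      ", estimators: ", paste(x$estimators, collapse = ", "),
      " (seed ", x$seed, ")\n", sep = "")
  if (x$n_redrawn)
    cat("  ", x$n_redrawn, "redraw(s) after non-convergence;",
        length(x$failed), "replication(s) flagged\n")
  print(sim_metrics(x))
  invisible(x)
}
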