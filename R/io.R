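#' Read observation-level data for an LV-CRM analysis
#'
#' Reads a CSV with a header row, restricts to the columns the
#' specification references (when given), applies complete-case deletion
#' with a logged count of removed rows, and validates the outcome as a
#' non-negative integer count.
#'
#' @param path CSV file path.
#' @param spec optional [lvcrm_spec()]; when supplied, only its columns are
#'   kept and validated.
#' @param quiet suppress the dropped-row message.
#' @return a data frame.
#' @export
read_lvcrm_data <- function(path, spec = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("data file not found: ", path)
  data <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(spec)) {
    cols <- c(spec$outcome, spec$covariates,
              unlist(spec$measurement, use.names = FALSE))
    missing_cols <- setdiff(cols, names(data))
    if (length(missing_cols))
      stop("columns not found in ", path, ": ",
           paste(missing_cols, collapse = ", "))
    data <- data[cols]
  }
  cc <- stats::complete.cases(data)
  if (any(!cc)) {
    if (!quiet)
      message("dropped ", sum(!cc), " incomplete row(s); ", sum(cc),
              " remain")
    data <- data[cc, , drop = FALSE]
  }
  if (!nrow(data)) stop("no complete rows left after filtering")
  if (!is.null(spec)) {
    y <- data[[spec$outcome]]
    bad <- which(y < 0 | y != round(y))
    if (length(bad))
      stop("outcome '", spec$outcome, "' must be non-negative integers; ",
           "offending row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  data
}

#' Read a model specification from a YAML or JSON config
#'
#' The config mirrors [lvcrm_spec()]: blocks `outcome`, `measurement`
#' (latent -> indicator list), `covariates`, `interactions` (list of pairs
#' or `"all"`), `latent_covariate_interactions`, `family`, `scaling`, and
#' `constraints: fixed_reliability: {indicator: value}`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an [lvcrm_spec()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  fr <- cfg$constraints$fixed_reliability
  if (!is.null(fr)) fr <- unlist(fr)
  ints <- cfg$interactions
  if (!is.null(ints) && !identical(ints, "all") && !is.list(ints))
    ints <- apply(as.matrix(ints), 1, identity, simplify = FALSE)
  lci <- cfg$latent_covariate_interactions
  if (!is.null(lci) && !is.list(lci))
    lci <- apply(as.matrix(lci), 1, identity, simplify = FALSE)
  lvcrm_spec(outcome = cfg$outcome,
             measurement = lapply(cfg$measurement %||% list(), unlist),
             covariates = cfg$covariates %||% character(),
             interactions = ints,
             latent_covariate_interactions = lci,
             family = cfg$family %||% "poisson",
             scaling = cfg$scaling %||% "standardized",
             fixed_reliability = fr)
}

#' Write a specification to a YAML config
#'
#' @param spec an [lvcrm_spec()].
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(spec, path) {
  stopifnot(inherits(spec, "lvcrm_spec"))
  cfg <- list(outcome = spec$outcome,
              measurement = lapply(spec$measurement, as.list),
              covariates = as.list(spec$covariates),
              interactions = lapply(spec$interactions, as.list),
              latent_covariate_interactions =
                lapply(spec$latent_covariate_interactions, as.list),
              family = spec$family, scaling = spec$scaling)
  if (!is.null(spec$fixed_reliability))
    cfg$constraints <- list(fixed_reliability =
                              as.list(spec$fixed_reliability))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write fit or simulation results
#'
#' Serializes a fitted model (`lvcrm_fit` / `lvcrm_glm`) or a Monte-Carlo
#' run (`lvcrm_sim`) to machine-readable JSON with full metadata (options,
#' seed, quadrature points, convergence) and, optionally, the parameter or
#' metric table as CSV. Field order is deterministic.
#'
#' @param x the object to write.
#' @param path output JSON path.
#' @param csv optional CSV path for the table.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, csv = NULL) {
  if (inherits(x, c("lvcrm_fit", "lvcrm_glm"))) {
    tab <- x$coefficients
    payload <- list(
      type = if (inherits(x, "lvcrm_fit")) "lvcrm" else "glm",
      family = x$family,
      estimates = stats::setNames(as.list(tab$estimate), tab$parameter),
      se = stats::setNames(as.list(tab$se), tab$parameter),
      ci = stats::setNames(lapply(seq_len(nrow(tab)), function(i)
        c(tab$lower[i], tab$upper[i])), tab$parameter),
      loglik = x$loglik,
      converged = isTRUE(x$converged),
      iterations = x$iterations %||% NA,
      options = list(M = x$M %||% NA,
                     control = x$control %||% NULL),
      package_version = as.character(utils::packageVersion("lvcrm")))
  } else if (inherits(x, "lvcrm_sim")) {
    tab <- sim_metrics(x)
    payload <- list(
      type = "simulation", study = x$design$study, R = x$R,
      seed = x$seed, M = x$M, estimators = x$estimators,
      n_redrawn = x$n_redrawn, failed = x$failed,
      spillover = as.list(attr(tab, "spillover")),
      rel_efficiency = as.list(attr(tab, "rel_efficiency") %||% list()),
      metrics = tab,
      package_version = as.character(utils::packageVersion("lvcrm")))
  } else stop("don't know how to write a ", class(x)[1])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  invisible(path)
}
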