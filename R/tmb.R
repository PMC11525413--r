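## Glue between the validated model and the compiled objective.

tmb_data <- function(model, M) {
  p <- model$p
  if (p) {
    rule <- gauss_hermite_rule(M)
    ix <- as.matrix(do.call(expand.grid, rep(list(seq_len(M)), p)))
    nodes <- matrix(rule$nodes[ix], ncol = p)
    logw <- rowSums(matrix(log(rule$weights)[ix], ncol = p))
  } else {
    nodes <- matrix(0, 1, 0)
    logw <- 0
  }
  list(y = model$y,
       Z = unname(model$Z),
       W = unname(model$W),
       load_lat = as.integer(model$load_lat - 1L),
       family = if (model$family == "poisson") 0L else 1L,
       nodes = nodes,
       logw = logw,
       gi_k = as.integer(model$gi[, 1] - 1L),
       gi_l = as.integer(model$gi[, 2] - 1L),
       om_lat = as.integer(model$om[, 1] - 1L),
       om_cov = as.integer(model$om[, 2]),   # column of Z, 0-based => idx
       rel_idx = as.integer(model$rel_idx - 1L),
       rel_val = model$rel_val)
}

## natural-scale lvcrm_params -> objective parameter list
tmb_par <- function(params, model) {
  list(beta = as.numeric(params$beta),
       gamma = as.numeric(params$gamma),
       gammaI = if (nrow(model$gi)) as.numeric(params$Gamma[model$gi])
                else numeric(0),
       omega = if (nrow(model$om)) as.numeric(params$Omega[model$om])
               else numeric(0),
       nu = as.numeric(params$nu),
       lambda = as.numeric(params$lambda),
       logtheta = if (model$q) as.numeric(log(params$theta)) else numeric(0),
       mu_eta = as.numeric(params$mu_eta),
       logsd_eta = if (model$p) 0.5 * log(diag(params$Sigma_eta))
                   else numeric(0),
       corr_tr = if (model$p >= 2)
         cor_to_tr(stats::cov2cor(params$Sigma_eta)) else numeric(0),
       logdisp = if (!is.null(params$dispersion)) log(params$dispersion)
                 else 0)
}

tmb_map <- function(model) {
  f <- model$free
  mk <- function(mask) factor(ifelse(mask, seq_along(mask), NA))
  map <- list()
  if (any(!f$nu)) map$nu <- mk(f$nu)
  if (any(!f$lambda)) map$lambda <- mk(f$lambda)
  if (any(!f$logtheta)) map$logtheta <- mk(f$logtheta)
  if (any(!f$mu_eta)) map$mu_eta <- mk(f$mu_eta)
  if (any(!f$logsd_eta)) map$logsd_eta <- mk(f$logsd_eta)
  if (!f$logdisp) map$logdisp <- factor(NA)
  map
}

make_objective <- function(model, start_params, M) {
  TMB::MakeADFun(data = tmb_data(model, M),
                 parameters = tmb_par(start_params, model),
                 map = tmb_map(model),
                 DLL = "lvcrm", silent = TRUE)
}

## --- native evaluator (hand-coded likelihood + analytic gradient) --------

## fill a block parameter list from the free vector (fixed slots keep the
## template's values); same free-slot order as the free parameter vector
par_blocks <- function(v, model, template) {
  f <- model$free
  i <- 0L
  tk <- function(k) {
    out <- v[i + seq_len(k)]
    i <<- i + k
    out
  }
  b <- template
  b$beta[] <- tk(model$m + 1L)
  if (model$p) b$gamma[] <- tk(model$p)
  if (nrow(model$gi)) b$gammaI[] <- tk(nrow(model$gi))
  if (nrow(model$om)) b$omega[] <- tk(nrow(model$om))
  if (any(f$nu)) b$nu[f$nu] <- tk(sum(f$nu))
  if (any(f$lambda)) b$lambda[f$lambda] <- tk(sum(f$lambda))
  if (any(f$logtheta)) b$logtheta[f$logtheta] <- tk(sum(f$logtheta))
  if (any(f$mu_eta)) b$mu_eta[f$mu_eta] <- tk(sum(f$mu_eta))
  if (any(f$logsd_eta)) b$logsd_eta[f$logsd_eta] <- tk(sum(f$logsd_eta))
  if (any(f$corr_tr)) b$corr_tr[] <- tk(sum(f$corr_tr))
  if (f$logdisp) b$logdisp <- tk(1L)
  stopifnot(i == length(v))
  b
}

## gather the full-block gradient into the free-vector order
free_gradient <- function(g, model) {
  f <- model$free
  c(g$beta,
    if (model$p) g$gamma,
    if (nrow(model$gi)) g$gammaI,
    if (nrow(model$om)) g$omega,
    g$nu[f$nu], g$lambda[f$lambda], g$logtheta[f$logtheta],
    g$mu_eta[f$mu_eta], g$logsd_eta[f$logsd_eta],
    if (any(f$corr_tr)) g$corr_tr,
    if (f$logdisp) g$logdisp)
}

native_objective <- function(model, start_params, M) {
  dat <- tmb_data(model, M)
  template <- tmb_par(start_params, model)
  list(
    par = pack_parameters(start_params, model),
    fn = function(v) {
      .Call("lvcrm_nllgrad", par_blocks(v, model, template), dat, FALSE,
            PACKAGE = "lvcrm")$nll
    },
    gr = function(v) {
      res <- .Call("lvcrm_nllgrad", par_blocks(v, model, template), dat,
                   TRUE, PACKAGE = "lvcrm")
      free_gradient(res$grad, model)
    })
}
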