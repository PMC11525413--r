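---
title: "Count regression with latent interactions: model, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count regression with latent interactions: model, estimation and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcrm)
```

## The model

`lvcrm` fits count regressions in which some predictors are latent
constructs measured by fallible indicators. The model has four parts.

**Random component.** Each count $Y_i$ is Poisson, $Y_i \sim
\mathcal P(\mu_i)$, or NB2 negative binomial with size (dispersion)
$\theta$, so that $\mathrm{Var}(Y_i) = \mu_i + \mu_i^2/\theta$. The NB2
family is the practical default for over-dispersed outcomes such as
symptom counts.

**Linear predictor.** With manifest covariates $z_i$ (leading constant
included) and latent variables $\eta_i \in \mathbb R^p$,

$$\pi_i = z_i\beta + \gamma'\eta_i + \eta_i'\Gamma\eta_i +
  \eta_i'\Omega z_i,$$

where $\Gamma$ is strictly upper triangular: each active entry
$\gamma_{kl}$ ($k < l$) is a latent-by-latent product term, and each
active $\omega_{jk}$ a latent-by-manifest product term. Latent squares
are deliberately excluded; the package models two-way products between
*distinct* predictors only.

**Link.** $\mu_i = \exp(\pi_i)$, the log link, which respects the lower
bound of counts at zero.

**Measurement model.** The $q$ indicators follow a congeneric linear
factor model $w_i = \nu + \Lambda\eta_i + \epsilon_i$ with
$\epsilon_i \sim N(0, \Theta)$, $\Theta$ diagonal, and $\eta_i \sim
N(\mu_\eta, \Sigma_\eta)$, independent of $\epsilon_i$. Each indicator
loads on exactly one latent variable; cross-loadings and correlated
errors are out of scope.

The scientific point of the joint model is *de-attenuation*: replacing
latent variables by fallible scores shrinks regression coefficients
toward zero, and products of fallible scores are even less reliable than
their factors, so product-term coefficients suffer most. Modeling the
measurement error removes this bias at the price of distributional
assumptions and heavier computation.

## Identification and scaling

A latent variable needs a scale. Two conventions are supported and give
equivalent models (identical maximized log-likelihoods; estimates map
onto each other by rescaling with the latent SDs, a property the test
suite checks):

* **standardized** (default): $\mu_\eta = 0$, $\mathrm{diag}(\Sigma_\eta)
  = 1$; all loadings and intercepts free. Latent effects are then per-SD
  effects, directly comparable with z-standardized sum scores.
* **marker**: first loading 1 and first intercept 0 per latent; latent
  means and variances free.

Latent correlations are freely estimated under both conventions. Wald
inference is not invariant to the scaling choice, which is one reason the
standardized convention is the default throughout the simulations.

`validate_spec()` applies counting rules per measurement block. The
practically important special case is a **fixed-reliability single
indicator**: one indicator, reliability fixed at a known value (e.g. a
published retest reliability), with the error variance constrained to
$\mathrm{Var}(\epsilon_k) = \lambda_k^2\,\mathrm{Var}(\eta)\,(1/\mathrm{Rel}
- 1)$. The constraint is re-evaluated from its drivers at every
optimizer step, never frozen at the starting values. Under standardized
scaling ($\mathrm{Var}(\eta) = 1$) this is the familiar
$\lambda^2(1/\mathrm{Rel}-1)$; the extra variance factor makes the same
constraint correct under marker scaling.

## Marginal likelihood and quadrature

The latent variables are integrated out of each case-wise likelihood:

$$\mathcal L_i = \int f(y_i \mid z_i, \eta)\, f(w_i \mid \eta)\,
  f(\eta)\, d\eta
  \;\approx\; \sum_{j=1}^{M^p} \omega_j\, f(y_i \mid z_i, \eta_j^*)\,
  f(w_i \mid \eta_j^*).$$

The rule is a tensor product of 1-D probabilists' Gauss–Hermite rules.
Standard-normal product nodes $z_j^*$ are fixed once; the latent-scale
nodes are $\eta_j^* = \mu_\eta + L z_j^*$ with $L L' = \Sigma_\eta$, so
the grid follows the current latent mean and covariance at every
iteration and the weights never involve the latent density itself. The
product terms in $\pi_i$ are evaluated *at the nodes*; no product
indicators or auxiliary measurement equations are ever introduced. The
node sum is accumulated as a log-sum-exp with the node maximum as the
scaling constant, which keeps rows with large counts or extreme
indicator patterns from underflowing. With $p = 0$ the sum collapses to
a single node and the model reduces exactly to the GLM (estimates and
standard errors agree with `stats::glm()` to numerical precision, also a
test).

**Choosing $M$.** The default in `lvcrm_fit()` is $M = 15$ points per
dimension. The quantity that matters is the width of the posterior of
$\eta$ given its indicators relative to the prior over which the grid is
laid out: with unit loadings and sum-score reliability $\rho$, the
posterior variance of a standardized latent given its indicators is
$1 - \rho$, i.e. a posterior SD of about 0.45 at $\rho = .8$ and 0.32 at
$\rho = .9$, against prior SD 1. A non-adaptive rule therefore needs a finer grid the more
reliable the indicators are: in the package's own checks, $M = 7$–$9$ is
accurate for $\rho \le .8$, while $\rho = .9$ needs $M \ge 15$ for the
product-term coefficient. The Monte-Carlo engine defaults to $M = 9$
(its built-in study conditions that involve fitting the latent model use
$\rho \le .8$); anything involving reliability .9 should raise it. An
adaptive (posterior-centered) variant is not implemented; tensor grids
are refused above $p = 3$, where their cost grows impractically.

## Optimization, starting values, standard errors

The objective and its exact analytic gradient are evaluated in compiled
code (`src/nllgrad.cpp`); an independent automatic-differentiation
implementation of the same objective (TMB template, `src/lvcrm.cpp`,
`engine = "ad"`) is kept in the package and the test suite requires the
two gradients to agree to ~1e-7 across families, scalings and constraint
patterns. Optimization uses the PORT quasi-Newton code
(`stats::nlminb`), with convergence declared at a relative
log-likelihood change below 1e-8 (`control$rel_tol`), a cap of 500
iterations, and the gradient infinity norm reported in the fit object.

Starting values are two-step: measurement parameters from a
principal-axis moment fit per indicator block (single-indicator blocks
use the fixed reliability), then structural parameters from a count GLM
on regression factor scores; the NB dispersion starts at the sum-score
`glm.nb` estimate. Internally the free parameters live on transformed
scales — log error variances, log latent SDs, log dispersion, and the
latent correlation factor through a row-normalised unit lower triangle —
so the optimizer is unconstrained.

Standard errors invert the observed information, obtained by finite
differences of the analytic gradient at the optimum; a non-invertible
information matrix is reported together with the parameter loading on
its weakest eigen-direction, which is the usual symptom of an
empirically under-identified latent block. Wald intervals are
$\hat\theta \pm z_{(1+\alpha)/2}\,\mathrm{SE}$.

## Interaction effects

In a log-link model the effect of one predictor depends on all others
even without product terms. The package therefore reports interaction
effects as the second-order mixed partial derivative of the mean
function,

$$\zeta_{jk}(x) = \frac{\partial^2 \exp(\pi)}{\partial x_j\,\partial x_k}
  = \exp(\pi)\,\bigl[c_j(x)\,c_k(x) + b_{jk}\bigr],$$

with $c_j$ the total first-order coefficient of $x_j$ at the point and
$b_{jk}$ the product-term coefficient (zero if absent). The first term
is the "natural" (model-inherent) interaction: it is non-zero whenever
both predictors matter, even with $b_{jk} = 0$, and it varies over the
predictor space. `interaction_effect()`, `conditional_regression()` and
`representative_points()` evaluate $\zeta$ at user-chosen points —
by default a $\{-2,-1,0,1,2\}$ grid on the standardized latent scale
with manifest covariates at their sample means, the "representative
points" convention. Standard errors come from the delta method with a
numerical gradient of $\zeta$ in the free parameters; the test suite
checks them against a parametric-simulation oracle. Covariate means are
treated as fixed constants: the sampling variance of an estimated mean
is *not* propagated, and sample-average effects over the latent
distribution are not computed (they would require integrating the
partial-derivative framework over the latent posterior, which is left
out of scope).

## The sum-score GLM baseline

The comparison estimator replaces each latent variable by the
z-standardized row sum of its indicators (sample mean/SD, denominator
$n-1$), forms product columns from the standardized scores
(standardize-then-multiply), and fits the count GLM: IRLS for Poisson
(`stats::glm`), IRLS alternating with ML for the NB dispersion
(`MASS::glm.nb`). Coefficients are reported under the same names as the
LV-CRM's, so bias and coverage comparisons are mechanical.

## The Monte-Carlo engine and its data-generating processes

`sim_design()` encodes three study families:

1. **Study 1** — Poisson outcome; two standard-normal latent predictors,
   correlation .3, three unit-loading, zero-intercept indicators each;
   $\pi = 0.2 + 0.3\eta_1 + 0.3\eta_2 + \gamma_{12}\eta_1\eta_2$ with
   $\gamma_{12} \in \{-0.3, 0, 0.3\}$; sum-score reliabilities from
   $\{.7, .8, .9\}$ set via the indicator error variances
   ($\theta = (\sum\lambda)^2(1-\rho)/(k\rho)$); $N$ from 100 to 1000.
2. **Study 2** — study 1 plus three independent, perfectly reliable
   N(0,1) covariates with coefficients 0.2 each, and an NB2 outcome with
   dispersion 2. This design measures spill-over (the Euclidean norm $S$
   of the three covariate-coefficient biases) and interval calibration.
3. **Study 3** — three latent predictors, all three pairwise product
   terms, $N = 500$; correlation and interaction patterns all-negative,
   all-positive, all-zero, or mixed $(-0.3, 0.3, 0)$.

The structural intercept 0.2, latent main effects 0.3, study-2 covariate
coefficients 0.2 and NB dispersion 2 are package defaults chosen as
typical small-to-moderate effects on the log scale (every one of them is
an argument of `sim_design()`); the printed design quantities —
correlation .3, reliabilities, $\gamma_{12}$ grid, sample sizes — are
fixed study conditions. One run generates data, fits one or both
estimators, redraws a replication (with a derived seed) if an estimator
fails to converge, and aggregates bias, relative bias, RMSE, relative
efficiency (RMSE ratio LV-CRM/GLM), CI coverage, detection rate and
spill-over. Every replication seed is a deterministic 32-bit hash of
(base seed, replication, redraw), so runs are exactly reproducible.

What the generator emulates is the *structure* of a psychometric count
regression: continuous congeneric indicators with normal errors, normal
latent variables, and a correctly specified outcome family. Real
questionnaire data differ in ways the generator deliberately ignores —
Likert-type discreteness and floor effects in the indicators, non-normal
latent distributions, missing responses (the package only does
complete-case deletion at ingestion), and outcome families beyond
Poisson/NB2 (e.g. zero inflation). Passing simulations therefore
demonstrate correctness of the estimator under its own assumptions, not
robustness to their violation.

A replication-scale note: the package's acceptance checks run the study
conditions at 200–500 replications per cell (the full published-style
grids at 1000 replications are an overnight job, not a test), with
$M = 9$ for the fitted latent models; these sizes are stated in the
tests themselves.

## Numerical and design choices worth knowing about

* **Native + AD double implementation.** The hand-coded evaluator is
  roughly an order of magnitude faster per gradient than the AD tape,
  which is what makes replication studies with per-fit standard errors
  practical on one core; the AD path is retained both as a user option
  and as the strongest available correctness oracle for the gradient.
* **Correlation parameterization.** $\Sigma_\eta = D\,L_c L_c'\,D$ with
  $L_c$ a row-normalised unit lower triangle keeps the optimizer
  unconstrained and is exactly invertible, so packing and unpacking
  parameters is a bijection (property-tested over 1000 random vectors).
* **Ties to the GLM.** `glm_baseline()` deliberately *buys* its fitting
  from `stats::glm`/`MASS::glm.nb` rather than reimplementing IRLS; the
  LV-CRM with $p = 0$ reproduces those fits, which pins the outcome
  log-density and its derivatives to a reference implementation.
* **Degenerate inputs.** Zero-variance sum scores, non-integer or
  negative outcomes, unidentified blocks, non-SPD correlation inputs and
  non-finite integrands are hard errors with the offending column, row
  or latent named; non-convergence of a fit is a flag, not an error.
* **Known limitations.** Non-adaptive quadrature degrades as
  $\Theta \to 0$ (the integrand approaches a point mass the prior-based
  grid cannot resolve) — very high reliabilities need large $M$, and
  exactly error-free indicators should simply be entered as manifest
  covariates. Tensor grids limit $p \le 3$. No cross-loadings,
  correlated errors, categorical indicators, multiple outcomes or
  multigroup structure.
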