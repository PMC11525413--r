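# lvcrm — latent variable count regression with latent interactions

`lvcrm` is for researchers who regress a **count outcome** (symptom
frequencies, event counts, numbers of drinks/arrests/visits) on
psychological constructs that are measured with error — questionnaire
scales, test scores, event checklists — and who care about
**interactions** between those constructs.

The usual practice is a Poisson or negative binomial GLM on
z-standardized sum scores. Measurement error then attenuates the
coefficients toward zero, and the product of two fallible scores is less
reliable than either factor, so interaction coefficients are hit
hardest. `lvcrm` instead fits the **latent variable count regression
model**: a count GLM whose linear predictor contains latent variables
defined by a congeneric factor model,

```
y_i  ~  Poisson(mu_i)   or   NB2(mu_i, theta)
log mu_i = z_i' beta + gamma' eta_i + eta_i' Gamma eta_i + eta_i' Omega z_i
w_i      = nu + Lambda eta_i + eps_i,   eta_i ~ N(mu_eta, Sigma_eta)
```

with latent-by-latent (`Gamma`, strictly upper triangular) and
latent-by-manifest (`Omega`) product terms. Estimation is marginal
maximum likelihood: the latent variables are integrated out of each
case-wise likelihood with tensor-product Gauss–Hermite quadrature, and
the objective plus its exact analytic gradient run in compiled code (an
independent automatic-differentiation implementation of the same
likelihood is kept in the package as a cross-check). The package also
provides:

* the **sum-score GLM baseline** (`glm_baseline()`) for like-for-like
  comparisons;
* pointwise **interaction effects** `zeta_jk = d^2 exp(pi) / dx_j dx_k`
  with delta-method CIs, conditional-regression (simple-slope) curves
  and representative-point tables (`interaction_effect()`,
  `conditional_regression()`, `representative_points()`) — in a
  log-link model these are non-zero even without a product term;
* a seeded **Monte-Carlo engine** (`sim_design()`, `simulate_lvcrm()`,
  `run_simulation()`, `sim_metrics()`) measuring bias, relative bias,
  RMSE, relative efficiency, CI coverage, detection rates and the
  spill-over statistic `S` for both estimators;
* fixed-reliability **single-indicator latent variables**
  (`fixed_reliability = c(score = 0.82)`) for predictors with a known
  retest reliability;
* CSV/YAML/JSON I/O and a small command-line front end
  (`inst/cli/lvcrm.R`: `fit`, `glm`, `simulate`, `effects`).

## Worked example

A synthetic clinical-style dataset: dissociative-symptom counts
(`symptoms`, NB2), a 5-item mental-defeat scale (`md1..md5`, latent
`MD`), and a trauma-exposure checklist score (`trauma`) treated as a
single-indicator latent `TL` with its reliability fixed at 0.82.

```r
library(lvcrm)

spec <- lvcrm_spec(
  outcome = "symptoms",
  measurement = list(MD = paste0("md", 1:5), TL = "trauma"),
  interactions = list(c("MD", "TL")),
  family = "negbin",
  fixed_reliability = c(trauma = 0.82))

glm_fit <- glm_baseline(d, spec)   # sum-score NB GLM
fit     <- lvcrm_fit(d, spec)      # marginal ML
print(fit)
```

```
Latent variable count regression (negbin, log link)
Marginal ML, 15 Gauss-Hermite points per dimension; log-likelihood -3199.5513
Converged in 21 iterations; max |gradient| = 0.0213

        parameter estimate      se   lower    upper      z   p_value
 beta_(Intercept)   0.8211 0.07431  0.6755  0.96675 11.050 2.185e-28
         gamma_MD   0.4459 0.07874  0.2916  0.60026  5.663 1.487e-08
         gamma_TL   0.2812 0.07975  0.1249  0.43748  3.526 4.222e-04
      gamma_MD:TL  -0.2207 0.08405 -0.3854 -0.05596 -2.626 8.645e-03
       dispersion   1.5669 0.25570  1.0657  2.06806  6.128 8.899e-10
... plus 23 measurement/latent parameters (see $coefficients)
```

Both latent main effects are positive (more mental defeat, more trauma
exposure → more symptoms) and the product term is negative: at high
trauma load, mental defeat differentiates less. The sum-score GLM gives
`gamma_MD:TL = -0.208 (SE 0.070)` — closer to zero, with an interval
that is too narrow because it ignores the measurement error the LV-CRM
accounts for.

Because the model is nonlinear, the interaction *effect* varies over the
predictor space; the representative-point table makes that concrete:

```r
representative_points(fit, values = -2:2)
```

```
Interaction effects zeta(MD, TL) at representative points (* : 95% CI excludes 0)
       MD=-2  MD=-1   MD=0   MD=1   MD=2
TL=2   -0.86  -0.87  -0.88 -0.88* -0.89*
TL=1   -0.11  -0.26  -0.47 -0.78*  -1.2*
TL=0  0.095* 0.0045  -0.22  -0.69   -1.6
TL=-1  0.12*   0.1* -0.057   -0.6   -2.1
TL=-2 0.092*  0.12*  0.037  -0.53   -2.8
```

Each cell is the instantaneous change of the `MD` slope (on the count
scale) per unit of `TL` at that point: positive and significant below
the mean of both constructs, strongly negative at high `MD` and `TL`.
`conditional_regression(fit, "MD", "TL")` returns the matching
simple-slope curves as plot-ready data.

The Monte-Carlo engine reproduces the attenuation story in a few lines:

```r
design <- sim_design(study = 1, n = 1000, reliabilities = c(.8, .8),
                     gamma_int = -0.3)
sim <- run_simulation(design, R = 200, seed = 1)
sim_metrics(sim)   # GLM product term biased toward zero; LV-CRM not
```

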