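---
title: "Marginal predictions from random-intercepts logistic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal predictions from random-intercepts logistic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustrisk)
```

## The problem

Clustered binary outcomes — patients within hospitals, pupils within
schools — are commonly analysed with a logistic random-intercepts model:

$$\mathrm{logit}\,P(Y_{ij}=1 \mid x_{ij}, u_i)
  = \alpha_{RE} + u_i + x_{ij}^\top \beta_{RE},
  \qquad u_i \sim N(0, \sigma_u^2),$$

where $i$ indexes clusters and $j$ members.  The fixed effects
$(\alpha_{RE}, \beta_{RE})$ are *conditional* (cluster-specific)
parameters.  A *marginal* (population-average) model,
$\mathrm{logit}\,P(Y_{ij}=1 \mid x_{ij}) = \alpha_M + x_{ij}^\top \beta_M$,
describes the same population without conditioning on $u_i$; its
coefficients are attenuated, $|\beta_{M,m}| \le |\beta_{RE,m}|$, with the
gap growing in $\sigma_u^2$.  A useful closed-form link is
$\beta_M \approx \beta_{RE} / \sqrt{c^2 \sigma_u^2 + 1}$ with
$c = 16\sqrt{3} / (15\pi) \approx 0.588$.

For a new individual in a *new* cluster the relevant predicted risk is the
marginal one.  From a fitted random-intercepts model it must be computed by
integrating over the random-effects distribution,

$$\hat\pi(\mathrm{int}) = \int
  \mathrm{expit}(\hat\alpha_{RE} + u + x^\top \hat\beta_{RE})\,
  \phi(u; 0, \hat\sigma_u^2)\, du,$$

not by plugging in the mean random effect,
$\hat\pi(0) = \mathrm{expit}(\hat\alpha_{RE} + x^\top \hat\beta_{RE})$.
The plug-in shortcut uses conditional coefficients as if they were
marginal ones, so its risks are too extreme: validated on individuals from
new clusters it shows a calibration slope below 1 and a non-zero
calibration-in-the-large, and the mis-calibration grows with the
intra-cluster correlation.  `clustrisk` implements both calculations, the
Zeger rescaling shortcut, GEE and plain MLE comparators, calibration
assessment, and a simulation study quantifying the mis-calibration.

## Fitting

`ri_logistic()` maximises the marginal likelihood in which each cluster's
random intercept is integrated out by Gauss–Hermite quadrature.  The
optimiser is BFGS on $(\alpha, \beta, \log\sigma_u)$ with an analytic
score, followed by Newton polishing to a score max-norm of `1e-8`.  The
log-sd parameterisation makes the variance boundary benign; estimates
below `1e-10` are reported as exactly 0, and a fit with
`fix_sigma_u2 = 0` is (verifiably) the ordinary logistic MLE.

Two quadrature settings matter:

* **Fitting order (default 51).**  The per-cluster integrand is the prior
  density times a likelihood that sharpens as the cluster grows; with ~50
  informative records per cluster its effective width is several times
  narrower than the prior.  Plain Gauss–Hermite centred at the prior needs
  enough nodes to resolve that peak: at the package's reference scale
  ($\sigma_u^2 \approx 1.4$, clusters of ~50) order 21 misestimates the
  log-likelihood by ~0.4 and $\hat\sigma_u^2$ by ~20%, order 51 is
  accurate to ~1e-5, and an adaptively centred rule (`adaptive = TRUE`,
  mode/curvature rescaling per cluster) is accurate already at low order
  but several times slower because the centring is iterative.  Order 51
  is the default; both variants are validated against brute-force
  integration in the tests.
* **Prediction order (default 41).**  The marginal-risk integrand
  $\mathrm{expit}(\eta + u)\,\phi(u)$ is smooth and no narrower than the
  prior, so a fixed rule centred at the prior converges very fast; order
  41 agrees with adaptive numerical integration to better than 1e-7
  across $|\eta| \le 5$, $\sigma_u^2 \le 3$.

`gee_logistic()` solves the estimating equations by Fisher scoring,
alternating with the moment estimator of the exchangeable correlation from
standardised residuals (dispersion fixed at 1; sandwich variance).  With
the independence working structure it reproduces `logistic_mle()` exactly,
as theory requires.  `logistic_mle()` and both calibration regressions use
one shared IRLS core with step-halving and explicit separation detection
(coefficient magnitude above 30 aborts with an error naming separation).

## Predictions

`predict()` on an `ri_fit` offers `re_zero`, `re_integ`, `re_approx`
(Zeger-rescaled linear predictor) and `conditional`.  Conditional
predictions serve new members of clusters already seen in training: the
cluster's random effect has a posterior given its observed outcomes, and
the risk is either the posterior-mean plug-in or, more correctly, the
posterior-weighted average of $\mathrm{expit}(\eta + u)$.  The posterior
is represented on the prior-scaled quadrature grid re-weighted by the
cluster likelihood; its mean is the empirical-Bayes estimate (mean rather
than mode, matching the integrated predictor's first moment; the mode is
also returned).  Risks are clipped to $[10^{-12}, 1 - 10^{-12}]$ before
any logit so calibration regressions stay finite.  For integrated methods
the reported linear predictor is `qlogis(risk)` by definition.

## Calibration

Following standard validation practice, `calibration()` reports

* the **calibration slope**, from the logistic regression of the outcome
  on the predicted log-odds (1 = correct dispersion; below 1 =
  predictions too extreme), and
* **calibration-in-the-large** (CITL), the intercept of an intercept-only
  logistic model with the predicted log-odds as offset (0 = average
  predicted risk matches prevalence; the intercept's sign says in which
  direction the average prediction misses: it is the shift that must be
  *added* to the predictions to recalibrate them on average).

Standard errors are model-based (observed information); the study module
reports empirical across-replicate SEs separately.  On the latent logistic
scale the ICC is $\sigma_u^2 / (\pi^2/3 + \sigma_u^2)$;
`icc_from_sigma2()` / `sigma2_from_icc()` are exact inverses.

## The synthetic source population

`sim_config()` defaults encode the reference study conditions: 100
centres with sizes $N_i \sim \mathrm{Poisson}(e^{\lambda_i})$,
$\lambda_i \sim N(5.7, 0.3^2)$ (mean size $\approx 312$; zero-size
centres are redrawn so the centre count stays fixed); three continuous
predictors $N(0, \mathrm{sd})$ with sds 1, 0.3, 0.2 and three binary ones
with prevalences 0.2, 0.3, 0.4; all coefficients 1 and intercept 0; and
$u_i \sim N(0, \sigma_u^2)$ with $\sigma_u^2$ set through the ICC.
Training sets arise by two-stage sampling — 20 centres drawn without
replacement, then 1000 members drawn as a simple random sample *pooled*
across those centres — and the validation set is the source population
with the 20 training centres removed, so validation is always on unseen
clusters.  The pooled reading of stage 2 is the closest literal one; an
equal-allocation variant (`stage2 = "stratified"`) is provided for
sensitivity.  A second scheme (`sampling_scheme = "dirichlet"`) generates
fresh training clusters with Multinomial sizes whose probabilities come
from a flat Dirichlet, for sensitivity to training/validation differences
in the cluster-size distribution; its clusters get fresh covariates,
intercepts and outcomes from the same laws.

The generator emulates the cluster structure, not everything about real
multicentre data: covariates are independent of each other, of the random
effects (no confounding by cluster) and of the cluster sizes (no
informative cluster size), and outcomes are complete.  Passing tests
therefore certify the marginalisation arithmetic and the calibration
behaviour under these conditions, not robustness to those violations.

## The simulation study

`run_study()` repeats, per ICC scenario in $\{0.05, 0.10, 0.15, 0.30\}$:
draw training/validation, fit the three models, compute the five marginal
prediction sets on the validation records, calibrate each.  Medians and
empirical standard deviations across 100 replicates are reported,
matching the usual presentation of such experiments; means are included
as well.  Failures are per-method, logged with reasons, and a scenario
with over 20% failures is flagged.

One design choice deserves note.  By default each replicate generates its
own source population (`fresh_population = TRUE`).  With a single shared
population the aggregated calibration is conditional on that population's
100 realised random intercepts, whose sample variance has a relative
standard deviation of about $\sqrt{2/99} \approx 14\%$; the median
calibration slopes then inherit a population-to-population wobble of
several hundredths, i.e. results would depend materially on the seed.
Regenerating the population per replicate estimates the design-averaged
quantity with the same per-replicate cost and much smaller seed
sensitivity.  The shared-population variant is available
(`fresh_population = FALSE`) for exact emulation of a fixed-population
experiment.

With these defaults the study shows the characteristic pattern: the naive
RE-zero predictions drift from a median slope just below 1 at ICC 0.05 to
roughly 0.79 at ICC 0.30 with a CITL magnitude around 0.14, while
RE-integ, RE-approx, GEE and plain MLE keep median slopes near 1 and CITL
near 0 at every ICC.  (Which side of zero the naive method's CITL lands
on depends on the sign of the average linear predictor; under these
generator defaults the average fixed-effect linear predictor is $+0.9$,
the naive predictions are on average too high, and the fitted offset
intercept is negative, $\approx -0.14$ at ICC 0.30.)  The numbers are
recomputed, not stored: `tests/testthat/test-acceptance.R` re-runs the
two extreme scenarios at full size and `scripts/acceptance.R` reproduces
the slope medians for all reported scenarios from a caller-supplied seed.

## Problem sizes and numerical choices

The test suite runs the full 100-replicate design for the ICC 0.05 and
0.30 scenarios and smaller configurations (fewer, smaller clusters) for
property checks — sizes chosen to exercise the same code paths at a scale
a desk check can afford.  Convergence tolerances: IRLS score max-norm
`1e-8` (calibration `1e-10`), GEE step and correlation-change `1e-8`,
random-intercepts score max-norm `1e-8`, all capped at 200 iterations.
Ties and degenerate cases: constant outcomes or constant predictors are
errors in calibration; a single cluster without `fix_sigma_u2` is an
error naming the non-identifiability; unknown clusters in conditional
prediction are errors pointing at marginal prediction.

## Limitations

Random slopes, non-Normal random effects and nested/crossed structures
are out of scope, as are weighted GEE for informative dropout,
discrimination metrics and flexible calibration curves.  The Zeger
rescaling is an approximation; its predictions differ from the integrated
ones by up to ~0.01 in risk at $\sigma_u^2 \approx 1.4$, which is why
both are provided.
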