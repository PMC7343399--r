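---
title: "Observer tolerance as a personality trait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer tolerance as a personality trait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidtrait)
```

## The problem

Behavioral field studies on habituated animals usually assume that human
observers are a neutral stimulus and that habituation is equal across group
members. Both assumptions can be probed with flight-initiation-distance (FID)
methodology: an observer approaches a focal animal directly at a controlled
pace and records the start distance (SD), the distance at which the animal
orients its gaze toward the observer (visual orientation distance, VOD), and
the distance at which it moves away (FID). If the distances at which
individuals orient and displace are repeatable within individuals, distinct
among individuals, and correlated across the two measures, then *tolerance of
observers* behaves like a personality trait — with direct consequences for how
observational data should be collected and interpreted.

`fidtrait` implements this analysis end to end: a synthetic-data generator
that reproduces the statistical structure of such a trial design, Bayesian
log-normal mixed models for VOD and FID (univariate and bivariate),
enhanced-agreement repeatability (ICC), the among-individual correlation
between the two tolerance measures, per-individual conditional modes,
PSIS-LOO predictive accuracy with Pareto $\hat k$ screening, and log-score
stacking to weigh the contribution of individual identity. Because raw trial
data of the motivating study design are not publicly deposited, the
generator is a first-class, tested component: every downstream claim is
validated by parameter recovery on data with known truth.

## The distance geometry and the constrained envelope

Each trial yields three distances ordered by construction:
$0 < \mathrm{FID} \le \mathrm{VOD} < \mathrm{SD}$ (approaches are only
started on animals not already looking, hence the strict upper inequality).
Two derived quantities control this "constrained envelope" in the models:

* **VODD** (VOD delay) $= \mathrm{SD} - \mathrm{VOD}$: ground covered before
  the animal orients;
* **VODI** (VOD interval) $= \mathrm{VOD} - \mathrm{FID}$: ground covered
  between orientation and displacement.

The source design describes these only graphically; the algebraic
definitions above are adopted throughout this package and flagged here
deliberately. The envelope induces heteroscedastic dependence between the
distance measures. Rather than modelling the truncation explicitly, the
analysis follows the established practice of conditioning on it: VODD enters
the VOD model (and VODI the FID model) as a fixed covariate *and* as an
individual-level random slope. Alternatives (quantile regression, the Phi
index, zero-intercept regressions) are deliberately out of scope.

## The models

Responses are strictly positive and right-skewed, so both are modelled
log-normally. On the log scale, for trial $n$ of individual $i$ on date $d$:

$$
\log y_n \sim \mathcal N\!\left(\mathbf x_n^\top \boldsymbol\beta
  + a_{d(n)} + \mathbf z_n^\top \mathbf u_{i(n)},\ \sigma^2\right)
$$

with fixed effects $\mathbf x_n$ = intercept, envelope covariate
(VODD or VODI), compatibility (VOD model: looking / not-engaged-not-looking
vs. engaged) or engagement (FID model), habitat (open vs. closed), height
(ground vs. above ground), number of neighbors within 5 m, neighbor-fled-first,
external events within 5 min, observer (unfamiliar vs. familiar), raw trial
number (1–12, not centred), and the observer × trial-number interaction —
the only interaction, because it captures per-observer habituation or
sensitization over repeated trials. The random structure is a date intercept
$a_d \sim \mathcal N(0, \tau^2)$ crossed with a correlated five-term
individual block
$\mathbf u_i \sim \mathcal N(\mathbf 0, \boldsymbol\Sigma)$ over intercept,
envelope-covariate slope, observer, trial number, and observer × trial
number. The bivariate model stacks both responses and shares a single
ten-term individual block, so all cross-response correlations — in
particular between the two intercepts — are estimated; residuals are
conditionally independent across responses given that block (the
among-individual correlation is derived solely from the individual-level
covariance, so a residual cross-correlation parameter is left out by
default).

### Priors

* fixed effects: $\mathcal N(0, 100^2)$ — effectively flat on the log scale;
* date and residual SDs: half-Student-$t$(df 3, scale 10) via the standard
  inverse-gamma auxiliary representation;
* the individual covariance $\boldsymbol\Sigma$: the Huang–Wand
  marginally-noninformative prior with $\nu = 2$ and scale 10. This choice
  makes every marginal correlation of the block exactly uniform on
  $[-1, 1]$ — the same marginal behaviour as an LKJ(1) prior, which is the
  conventional noninformative choice for correlation matrices — while the
  marginal SDs are half-$t$(df 2, scale 10). The df-2 (rather than df-3)
  tail on the block SDs is the price of exact conjugacy; both priors are
  essentially flat over the plausible range (SDs below ~1 on a log scale),
  and prior-sensitivity is negligible at 69 individuals.

### Posterior computation

The log-scale model is a Gaussian mixed model, so the posterior is explored
with a blocked Gibbs sampler (compiled C++ core): all full conditionals —
fixed effects, date effects, individual block, covariance, scalar variances —
are conjugate. Two features matter for mixing:

* **Collapsed fixed-effect updates.** $\boldsymbol\beta$ is drawn from its
  conditional with the individual block integrated out (a per-individual
  Woodbury identity), then $\mathbf u_i \mid \boldsymbol\beta$. Without
  this, the strong coupling between the envelope-covariate coefficient and
  its random slope makes plain alternation mix extremely slowly.
* **Scale moves on the block.** Weakly-informed variance components (e.g.
  random slopes near zero) mix slowly under centred conjugate updates. A
  Metropolis rescaling move $(\mathbf u_{\cdot k}, \Sigma_{k\cdot})
  \to (\alpha\,\mathbf u_{\cdot k}, \alpha\,\Sigma_{k\cdot})$ with a
  log-normal proposal and the exact prior/Jacobian acceptance ratio targets
  this direction directly. Three sweeps with proposal scales 0.1/0.3/0.8 run
  per iteration.

The sampler was cross-validated against an independent MCMC implementation
(JAGS) on a reduced random-intercept model with matched priors; posterior
means and SDs agree within Monte Carlo error (see the test suite).
Convergence is summarized by rank-normalized split-$\widehat R$ and
bulk/tail effective sample sizes per parameter; the convergence flag
requires $\widehat R \le 1.01$ and bulk ESS $\ge 400$ everywhere, and a fit
failing it is returned with a structured warning, never silently. Gibbs
samplers have no divergent transitions; the diagnostics above are the
relevant reliability checks. Default desk-scale settings are 4 chains ×
2000 iterations (500 warmup); final-inference runs should scale these up
(the correlations attached to near-zero SDs are the slowest-mixing
quantities).

## Variance decomposition and repeatability

All components live on the latent (log) scale, where the variance
components of a log-normal model are defined. Per posterior draw:

* $V_{\mathrm{ind}} = \frac1n\sum_n \mathbf z_n^\top \boldsymbol\Sigma\,
  \mathbf z_n$ — the individual block averaged over the observed design, so
  random slopes contribute through the observed covariate values;
* $V_{\mathrm{date}} = \tau^2$, $V_{\mathrm{res}} = \sigma^2$;
* $V_{\mathrm{fix}}$ — the *population* variance of
  $\mathbf X\boldsymbol\beta$ over the fitted rows.

The enhanced-agreement ICC is
$V_{\mathrm{ind}} / (V_{\mathrm{ind}} + V_{\mathrm{date}} +
V_{\mathrm{fix}} + V_{\mathrm{res}})$, summarized by the posterior mean and
a 95% highest-density interval (the narrowest contiguous interval holding
95% of sorted draws). Including $V_{\mathrm{fix}}$ is the
enhanced-agreement convention; a variant without it is exposed
(`include_fixed = FALSE`) because published descriptions of the denominator
are not always explicit about it. Zero-denominator draws are excluded with
a count rather than propagated as NaN.

The among-individual correlation from the bivariate fit is, per draw,
$\mathrm{cov}(u^{\mathrm{VOD}}_{0}, u^{\mathrm{FID}}_{0}) /
\sqrt{V(u^{\mathrm{VOD}}_{0})\, V(u^{\mathrm{FID}}_{0})}$ — covariance
standardized to $[-1, 1]$, which is asserted, not assumed. Conditional
modes default to the posterior *mean* of each individual's intercept
deviation: for MCMC output the mean is the stable summary, and for Gaussian
random effects the mode and mean coincide (the BLUP connection); a
kernel-density mode is available by option.

## Model comparison: is identity predictive?

Leave-one-out expected log predictive densities are computed from the
pointwise log-likelihood matrix (log-normal density including the Jacobian
of the log transform, evaluated per draw and observation) by Pareto-smoothed
importance sampling: per observation, the largest ~20% of importance ratios
(at least 5) are replaced by expected order statistics of a generalized
Pareto distribution fitted to the tail with the Zhang–Stephens
profile-posterior estimator. The fitted shape $\hat k$ is the reliability
diagnostic; observations with $\hat k > 0.7$ are counted and surfaced. A
degenerate tail (all ratios equal) reports $\hat k$ as NA with unsmoothed
weights.

Stacking weights maximize
$\sum_i \log \sum_k w_k \exp(\mathrm{elpd}_{ik})$ over the simplex — a
concave problem solved through a softmax parameterization with analytic
gradients; ties return uniform weights by a documented rule. The identity
comparison fits the maximal model and the same model with the *entire*
individual block removed, and stacks their predictive distributions: a
with-identity weight near 1 means identity improves prediction at
essentially every trial. WAIC, Bayes factors and pseudo-BMA are
deliberately not offered; stacking is the method of record for this
analysis ("M-open" reasoning).

## What the generator emulates — and what it does not

Defaults reproduce the study conditions this package targets: 69
individuals × 2 observers × 12 trials = 1656 trials over 58 dates (at most
two approaches per individual per day, observers interleaved within a day),
SD uniform on 2.5–33.8 m, fixed effects and variance components at the
fitted posterior means of the motivating study group (e.g. individual
intercept SDs 0.24/0.49, residual SDs 0.31/0.36, date SD 0.14), and an
among-individual intercept correlation of 0.875. Covariate frequencies
(40/35/25% compatibility split, half open habitat, 85% on ground, Poisson(1.2)
neighbors, 15% neighbor-fled-first, 5% external events) are not printed
anywhere in the source design and were chosen once as field-plausible
values; they matter only through $V_{\mathrm{fix}}$ and the design spread
of the envelope covariates. Response categories are drawn from the recorded
study frequencies (98.85% passive displacement).

Two structural choices deserve emphasis:

* **Envelope circularity.** VODD is simultaneously a predictor of VOD and a
  function of it. The generator breaks the circle by drawing a *draft*
  response from the covariate-only part of the model with independent
  noise; the resulting provisional VODD/VODI enters the generative linear
  predictor. Because the draft involves neither the random effects nor the
  final trial's noise, the provisional envelope covariate is exogenous with
  respect to everything the mixed model treats as random — the condition
  interval coverage relies on. The envelope is then enforced by rejection
  sampling (cap 1000, inverse-CDF truncated sampling as fallback) and the
  exact VODD/VODI are recomputed for the output table, so fitted models
  only ever see internally consistent rows.
* **The joint individual correlation.** The printed within-response
  correlation matrices are positive definite, but a joint 10×10 matrix
  coupling *only* the two intercepts at 0.875 is not. The generator couples
  the responses through a single shared factor on the intercept
  innovations: the cross block is $\rho\, \mathbf c_V \mathbf c_F^\top$
  with $\mathbf c_\bullet$ the first columns of the within-block
  correlations. This is positive semidefinite for any $|\rho| \le 1$ and
  leaves the intercept–intercept correlation exactly $\rho = 0.875$; the
  other cross-correlations are those induced through the intercept factor.

What passing tests on these data do **not** show about real data: the
generator has no spatial structure, no abandoned trials, no per-individual
SD preferences (intolerant animals refusing close approaches), no time-of-day
structure, and its covariates are independent across trials. Conclusions
about estimator calibration transfer; conclusions about field biology do not.

### Calibration is assessed where the likelihood is correctly specified

With the envelope enforced, the fitted log-normal likelihood is — by the
design of the analysis itself — a misspecified description of the truncated
generative law: the envelope is *controlled for* via covariates, not
modelled. Interval coverage of a posterior is a property of the
matched-model regime, so the recovery/coverage studies (and the
corresponding acceptance checks) run the generator with `envelope = "none"`,
in which the generative law equals the fitted likelihood exactly and the
stored envelope covariate is the exogenous provisional one. The
envelope-on mode is exercised by its own invariant (100% of rows satisfy
$0 < \mathrm{FID} \le \mathrm{VOD} < \mathrm{SD}$ across random
configurations) and by the constrained-data fits in the acceptance script.
A consequence worth knowing: under the constrained defaults the implied
latent-scale ICC is higher than in the unconstrained regime printed by the
motivating analysis, because the envelope-slope contribution
$\mathbb E[\mathrm{VODD}^2]\,\sigma^2_{\mathrm{slope}}$ is large when SD
spans 2.5–33.8 m. The package reports the config-implied ICC
([implied_icc()]) alongside the recovered one so that recovery is judged
against the right target.

## Numerical choices

* Truncated log-normal draws: rejection with a 1000-retry cap, inverse-CDF
  fallback; an error naming the offending row's parameters is raised only
  when the truncation mass underflows entirely.
* HDI: exact narrowest-window scan over sorted draws
  ($\lceil 0.95\,n\rceil$ of them).
* GPD tail fit: Zhang–Stephens with the usual weak shape regularization
  (pull toward 0.5 with prior weight 10); tail size
  $\max(5, \lfloor 0.2 S\rfloor)$, configurable.
* Stacking optimizer: BFGS on the softmax scale, gradient tolerance well
  below $10^{-8}$ on the objective; pure-dominance cases reach the vertex
  to solver tolerance.
* Individuals with fewer than 2 trials are retained (partial pooling
  handles them) with a recorded warning; unseen factor levels are errors;
  constant design columns are warnings stored in fit metadata.
* Scheduling: interleaved round-robin over dates, erroring when the
  two-per-day cap makes the requested design infeasible.

## Problem sizes used by the tests and the acceptance script

Unit tests run miniature designs (typically 8 individuals × 8 dates × 4
trials) with short chains — enough to exercise every code path and the
exact oracles. The recovery studies use the full 69 × 24 design with
reduced sampler settings (2 chains × 900 iterations, 300 warmup) over 20
replicates for coverage, and the acceptance script's headline fits use 2 ×
3000 (univariate) and 2 × 2500 (bivariate) draws. These sizes were chosen
as the smallest at which Monte Carlo error is comfortably below the
tolerances being checked; final scientific inference should use more
chains and iterations (and will simply take minutes rather than seconds).

## Known limitations

* At the study's group size (69 individuals) the posterior of an *extreme*
  among-individual correlation is noticeably shrunk toward zero by the
  block prior: with a generative intercept correlation of 0.875, posterior
  means average ≈ 0.77 across replicate simulations, and the bias falls to
  ≈ 0.04 at 250 individuals. The qualitative conclusion (a strong, clearly
  nonzero correlation — convergent validity) is recovered on every
  replicate, but point estimates of correlations this extreme should be
  read as conservative at this sample size; the same behaviour is expected
  of the LKJ-family priors conventional in this literature.

* The Gibbs sampler's slowest-mixing quantities are correlations attached
  to near-zero random-slope SDs; at desk-scale settings their ESS can sit
  in the tens while every fixed effect and the headline variance components
  mix well. The convergence flag reports this honestly; scale up iterations
  for publication-grade summaries of those specific parameters.
* The ICC is computed on the latent (log) scale only; an observation-scale
  approximation is out of scope.
* The bivariate model omits a residual cross-response correlation
  (switchable in principle, off by design here); if the data-generating
  process couples trial-level residuals, the among-individual correlation
  absorbs none of it.
* No frequentist repeatability path (ANOVA/likelihood-ratio) is provided.
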