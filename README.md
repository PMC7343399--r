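# fidtrait

Observer-tolerance personality analysis from flight-initiation-distance
(FID) trials.

## The problem

When a human observer approaches a wild animal directly at a controlled
pace, three distances describe the encounter: the start distance (SD), the
visual orientation distance (VOD — where the animal turns its gaze toward
the observer), and the flight initiation distance (FID — where it moves
away), ordered by construction as `0 < FID ≤ VOD < SD` (the "constrained
envelope"). Repeated trials on marked, habituated individuals turn these
distances into two candidate personality measures: *visual tolerance* (VOD)
and *displacement tolerance* (FID). If both are repeatable within
individuals, distinct among individuals, and strongly correlated with each
other, tolerance of observers is a personality trait — which undermines the
common assumptions that observers are a neutral stimulus and that
habituation is equal across group members.

`fidtrait` is for behavioral ecologists who want to run this analysis, or
to study its statistical properties before fielding it. It provides:

* a **synthetic trial generator** reproducing the sampling design
  (balanced individuals × observers × trials, a two-per-day cap over
  sampling dates, envelope-constrained log-normal distances, correlated
  individual random effects, known generative truth for recovery studies);
* a **behavioral-response framework** mapping the eight recorded response
  categories to the threat level an observer would have to represent, with
  exact tallies;
* **Bayesian log-normal mixed models** for VOD and FID (and a bivariate
  model sharing one individual-level block), fitted by a compiled blocked
  Gibbs sampler with collapsed fixed-effect updates — priors: Normal(0, 100)
  fixed effects, half-t scalar SDs, marginally-uniform correlations;
* **enhanced-agreement ICC** (repeatability) with 95% highest-density
  intervals, the **among-individual VOD–FID correlation** (convergent
  validity), and per-individual **conditional modes**;
* **PSIS-LOO** pointwise predictive accuracy with Pareto k-hat screening
  and **log-score stacking** to weigh whether individual identity is
  predictive;
* an end-to-end **pipeline** (`run_pipeline()`) writing every table and
  summary as CSV/JSON with reproducible seeds and a config hash.

The model, on the log scale, for trial *n* of individual *i* on date *d*:

```
log y_n ~ Normal( x_n' β + a_d(n) + z_n' u_i(n) , σ² )
u_i ~ MVN(0, Σ)   over (intercept, VODD/VODI slope, observer,
                        trial number, observer × trial number)
a_d ~ Normal(0, τ²)
```

with treatment-coded covariates (compatibility/engagement, habitat, height,
neighbors, external events, observer, trial number, observer × trial) and
the envelope controlled by the VODD (= SD − VOD) or VODI (= VOD − FID)
covariate plus its random slope. See the methods vignette
(`vignettes/tolerance-personality-methods.Rmd`) for priors, sampler design,
variance decomposition and the generator's assumptions.

## Worked example

```r
library(fidtrait)

cfg    <- sim_config(seed = 42)          # study-scale defaults: 69 x 2 x 12
trials <- simulate_trials(cfg)           # 1656 envelope-constrained trials

dplyr::filter(tally_responses(trials), n > 0)
#>   response_category      label                              n percent
#> 1 displacement_with_geck Displacement with geck/grimace    10    0.6
#> 2 passive_displacement   Animal passively displaces      1643   99.2
#> 3 flinch_before_flight   Flinch/startled before flight      3    0.18

fit <- fit_univariate(trials, model_spec("vod"), chains = 2, iter = 2000,
                      warmup = 500, seed = 1)
enhanced_icc(variance_components(fit))
#>   response grouping       mean hdi_low hdi_high n_draws n_excluded
#> 1 vod      individual_id 0.720   0.645    0.794    3000          0

bi <- fit_bivariate(trials, chains = 2, iter = 1500, warmup = 500, seed = 2)
among_individual_correlation(bi)
#>   parameter                          mean hdi_low hdi_high
#> 1 cor(vod_intercept, fid_intercept) 0.840   0.669    0.973

compare_identity_models(trials, model_spec("fid"), chains = 2, iter = 900,
                        warmup = 300, seed = 3)
#>   model              elpd    se n_high_khat   weight
#> 1 with_identity    -1309.  37.9           2 1   e+ 0
#> 2 without_identity -1970.  40.7           0 7.14e-65
```

Reading the output: roughly 99% of simulated trials end in passive
displacement (the generator draws categories at the recorded study
frequencies — the pattern expected of a dominant conspecific, not a
predator). The ICC says ~72% of latent-scale VOD variance is attributable
to consistent among-individual differences after accounting for date and
the fixed effects; the among-individual correlation of 0.84 (HDI 0.67–0.97,
generative truth 0.875) is the convergent-validity evidence that both
distances measure one underlying tolerance trait; and the stacking weight
of ~1 for the with-identity model says individual identity improves
out-of-sample prediction at essentially every trial. These are short-chain
demonstration settings — `glance(fit)` reports the convergence flag, and
final inference should scale chains/iterations up.

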