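# moodcast

Forecasting daily self-reported mood in bipolar disorder from smartphone
self-assessments, with hierarchical Bayesian regression.

Patients in smartphone-based monitoring programmes answer a short daily
questionnaire (mood on a 9-level ordinal scale from −3 depressed to +3
manic, plus activity, sleep, anxiety, irritability, cognitive difficulty,
stress, alcohol, medicine adherence and mixed mood). Forecasting tomorrow's
— or next week's — mood from a few days of such history supports early
intervention, but the data are short, noisy, irregularly missing, and come
from many different individuals at once. `moodcast` implements the
modelling and evaluation machinery for this task end-to-end, plus a
calibrated synthetic-cohort generator so the whole pipeline is testable
without access to clinical data.

## The models

For patient *j* and windowed example *i*, with **x**<sub>ji</sub> the
normalized self-assessments of the previous *w* days (12 predictors per
day) and *y*<sub>ji</sub> the raw mood at horizon *h*:

**Hierarchical linear regression** (partial pooling / multi-task learning):

- *y*<sub>ji</sub> ~ Normal(α<sub>j</sub> + β<sub>j</sub>ᵀ**x**<sub>ji</sub>, σ)
- α<sub>j</sub> ~ Normal(μ<sub>α</sub>, τ<sub>α</sub>),
  β<sub>j</sub> ~ Normal(μ<sub>β</sub>, τ<sub>β</sub>) component-wise

Each patient gets their own intercept and weights, shrunk toward population
distributions: with little individual data predictions fall back on the
population (solving the cold-start problem for new patients), and they
personalize as data accumulate. Mood-lag weights receive wider priors than
the other items; all scale parameters have half-normal priors; sampling
uses the non-centered parameterization (MCMC via JAGS, default 4 chains ×
5,000 iterations, half warm-up).

**Hierarchical ordered-logistic regression** treats the 9-level mood scale
as ordinal: a latent score *z*<sub>ji</sub> = β<sub>j</sub>ᵀ**x**<sub>ji</sub>
with patient-specific ordered cutpoints **c**<sub>j</sub> (partially pooled
around an ordered population location) defines category probabilities
through the logistic CDF. Its predictions and uncertainty bands can never
leave the range of the training data.

Baselines: last-observed mood, pooled/separate means, pooled/separate
ridge regression and gradient-boosted trees.

**Evaluation** uses two genuinely temporal cross-validation schemes —
leave-all-out (consecutive pooled partitions; trains strictly on the past)
and leave-one-out (a held-out patient's first two weeks pooled with
everyone else's data) — with predicted R² and RMSE pooled across test sets,
window-size and horizon sweeps, posterior-predictive tail checks against
the depressive (< −0.75) and manic (> 0.75) mood tails, and feature
importance via the mean absolute *t*-statistic of individual-level weights.

## Worked example

```r
library(moodcast)

# 1. simulate a cohort with the calibrated defaults scaled down
cfg <- population_config(n_patients = 12, n_days = 70, seed = 42)
cohort <- generate_population(cfg)
s <- summarize_population(cohort)
cat(sprintf("pooled mood: mean %.2f, SD %.2f; adherence %.0f%%\n",
            s$mood_mean, s$mood_sd, 100 * s$adherence))
#> pooled mood: mean -0.13, SD 0.54; adherence 82%

# 2. window the series: 2-day history, 1-day-ahead target
ds <- build_windows(cohort, w = 2, h = 1)
print(ds)
#> Forecast dataset: N=443 examples, J=12 patients, w=2 day(s), h=1 day(s), 24 features

# 3. leave-all-out time-series cross-validation, baseline suite vs hierarchy
plan <- make_leave_all_out_splits(ds, T = 5, partition_length = 7)
cv <- run_cv(list(
  last_observed = list(kind = "last_observed"),
  pooled_mean   = list(kind = "pooled_mean"),
  pooled_ridge  = list(kind = "pooled_ridge"),
  hier_linear   = list(kind = "hier_linear",
                       mcmc = mcmc_config(chains = 2, iterations = 800,
                                          seed = 7))),
  ds, plan, seed = 3)
print(cv)
#> Time-series cross-validation (leave_all_out)
#>          model      r2  rmse n_test n_folds n_excluded
#>  last_observed  0.1113 0.520    185       4          0
#>    pooled_mean -0.0613 0.568    185       4          0
#>   pooled_ridge  0.1220 0.517    185       4          0
#>    hier_linear  0.1734 0.501    185       4          0

# 4. fit on everything and rank predictors
fit <- fit_hier_linear(ds, mcmc = mcmc_config(4, 2000, seed = 11))
head(feature_importance(fit), 3)
#>       item lag mean_abs_t  sd_abs_t
#> 1     mood   0   4.356819 0.3230179
#> 2     mood   1   1.676775 0.1461033
#> 3 activity   0   1.575427 0.1634442
```

Reading the output: the mean model explains no out-of-sample variance
(R² ≈ 0, by construction of predicted R²); repeating the last observed mood
is a solid naive baseline; the hierarchical model attains the lowest RMSE
by pooling information across patients while keeping individual intercepts
and weights. Same-day mood is by far the most important predictor of
tomorrow's mood (largest mean |t| of the individual-level weights), as
expected given mood's strong positive autocorrelation. Short chains, as in
the CV step above, can emit non-convergence warnings (split-R̂ > 1.05 on a
population parameter); the fitted object records the diagnostics in
`$diagnostics`.

A command-line front-end over the same functions lives at
`inst/cli/moodcast.R` (subcommands `simulate`, `windows`, `fit`, `cv`,
`sweep-w`, `sweep-h`, `check`, `importance`, each driven by a JSON config
and writing its resolved config next to its artifacts).

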