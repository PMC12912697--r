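---
title: "Hierarchical global-local boosted mortality modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical global-local boosted mortality modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

An insurer operating in several countries observes, for each portfolio
record, a death count $D_i$, a time-at-risk exposure $E_i$ (life-years),
and a set of features. Some features — age, gender, calendar year, policy
duration, sum-assured band — are *global*: collected everywhere and
comparable across countries. Others — regional classifications,
occupation codes, underwriting categories — are *local*: country-specific
in meaning and availability. The modelling target is the mortality rate
$\mu(x)$, expected deaths per life-year, under the standard assumption

$$ D_i \sim \mathrm{Poisson}\big(\mu(x_i)\, E_i\big). $$

The practical tension is that large countries could support rich local
models on their own, while small countries (a few hundred deaths) cannot
— yet a single pooled model either discards local features or has to
contort them into a common representation. `mortboost` implements a
two-step compromise:

1. **Global step.** Pool all countries and fit one boosted Poisson rate
   model $q(x_{\text{global}})$ on the global features only.
2. **Local step.** For each country $j$, continue boosting *from the
   global model's predictions*: each record's initial score is
   $\log q(x_{\text{global}})$ and the country's ensemble is trained on
   its own records, using the global features plus whatever local
   features that country actually has.

The fitted expected death count factorises exactly:

$$ \widehat D_i \;=\; q(x_{i,\text{global}}) \; \times \;
   h_{j(i)}(x_i) \; \times \; E_i, $$

where $h_j$ is the country's multiplicative *residual factor*. With zero
local trees $h_j \equiv 1$ and the model degrades gracefully to the
global fit; this identity is enforced in code (the local stage's base
score is constrained to zero) and checked to machine precision in the
test suite.

## The weighted-rate device

Boosting backends optimise a per-record loss; an explicit offset term in
the Poisson log-likelihood is not always available. The package instead
uses the standard weighted-rate reformulation: train on the *rate*
target $D_i/E_i$ with record weight $E_i$ under the Poisson objective.
The weighted Poisson deviance of a rate prediction $\hat\mu$ is, up to
constants, identical to the offset model's deviance for
$\widehat D = \hat\mu E$, so the two formulations share gradients,
hessians, and optima. Two consequences are tested exactly:

* an intercept-only fit returns the maximum-likelihood portfolio rate
  $\sum D / \sum E$;
* a fit on a single categorical feature reproduces a Poisson GLM with
  offset (fitted independently by IRLS) to $10^{-4}$ relative error.

`fit_rate()` wraps the backend (`xgboost`, `count:poisson` objective,
leaf-wise growth via `grow_policy = "lossguide"` with a `max_leaves`
cap). Initial scores are supplied per record through `base_margin`, and
the same explicit margin is passed at prediction time so no
backend-estimated intercept can leak into predictions. Single-threaded
histogram building makes fits bit-reproducible for a given seed.

## Leaf-size constraints in death units

Actuarial practice constrains leaves by credibility: a leaf should hold
enough *expected deaths* to support its own rate estimate.
`learner_spec()` exposes `min_deaths_per_leaf` and
`min_exposure_per_leaf`; both are realised through the backend's
`min_child_weight`, which for the Poisson objective bounds the per-leaf
hessian — the sum of predicted deaths. The effective constraint is

```
min_child_weight = max(min_deaths_per_leaf,
                       min_exposure_per_leaf * portfolio_rate)
```

i.e. an exposure floor is converted to death units at the portfolio's
overall rate. This is a deliberate approximation: the backend offers no
direct exposure-per-leaf constraint, and expected deaths are the
credibility-relevant quantity anyway.

## Categorical features: out-of-fold target encoding

Categorical features are replaced by exposure-weighted conditional rates
(target encoding). Naive target encoding leaks each record's own target
into its feature; the package therefore fits, per feature, a full-data
map *plus* $k$ complement maps on fold complements (folds grouped by
country-year so that encoding, tuning, and evaluation share one fold
structure). Two transformation modes exist:

* `train_oof`: each record receives the encoding fitted on its fold's
  complement — its own target contributes *zero* (verified by a
  finite-perturbation test: perturbing record $i$'s target never moves
  record $i$'s encoding);
* `apply`: every record receives the full-training-mean encoding — a
  pure function of the training set, used for all held-out or production
  data.

**Where each mode is used.** Inside hyperparameter tuning, training
folds are encoded out-of-fold and held-out folds through
complement-fitted encoders, so model selection is leakage-safe. For the
*final deployed fit*, however, the package fits on apply-mode encodings.
The reason is numerical rather than statistical: fitting on OOF
encodings while predicting through apply-mode encodings evaluates the
exponential link at systematically shifted feature values, and with
sparse death counts this Jensen-style drift produced a material
calibration bias (training actual-over-expected of about 0.90 on the
scaled-down study portfolio). Fitting and predicting through the *same*
(apply-mode) encodings restores the Poisson balance property
$\sum \widehat D \approx \sum D$ on the training data. The final fit's
hyperparameters are still chosen leakage-safely, and the encodings are
means of thousands of records, so the residual self-fit effect is
negligible next to the calibration gain.

Missing values are sentinel-imputed before encoding — `"Missing"`
becomes an ordinary category with its own learned rate, and metric
features use the constant $-1$ (outside every generator's range).

## Partial pooling by deliberate under-convergence

The local step is where shrinkage happens, and it is controlled by the
learning budget rather than an explicit prior. After $K$ boosting rounds
at learning rate $\eta$, a constant log-residual $\delta$ (a country
whose level differs from the global structure by $e^\delta$) is captured
to approximately $1 - (1-\eta)^K$; the remainder stays pooled at the
global estimate. The study configuration uses $\eta = 0.05$, $K = 30$
for the local stage, retaining $(0.95)^{30} \approx 0.21$ of the
deviation unexplained — roughly 78% capture. Combined with
`min_deaths_per_leaf`, this gives the hierarchical behaviour one wants:
countries with heavy exposure move almost all the way to their own
experience, while a small country's local trees can barely split and its
predictions stay near the global pattern. The shrinkage tendency is
verified in the test suite on a two-country design with identical true
local deviations but a 20-fold exposure difference.

## Benchmark strategies

`run_benchmark()` compares four strategies on a train/test split,
reporting per-country Poisson log-likelihood (per record, on the death
scale) and RMSE of rates:

* `two_step` — the hierarchical model above;
* `local` — an independent boosted model per country, no pooling;
* `one_step_single` — one pooled model over global *and* local features,
  missing cells sentinel-imputed;
* `one_step_mice` — one pooled model per MICE-completed table,
  predictions pooled by averaging.

The MICE engine bootstraps the training table, then iterates over the
incompletely observed variables in schema order, fitting a decision tree
(`tree::tree`) per variable on the rows where it is observed and drawing
imputations uniformly from the observed values in each missing record's
leaf. The fitted trees also complete the test table — test rows are
never used for fitting, so the imputation itself cannot leak. Defaults
are 4 bootstrap resamples and 2 refinement iterations, giving 4
completed tables and 4 pooled models. Variables missing in *every*
record cannot be imputed from data; they stay sentinel-filled and are
flagged. One implementation note: high-cardinality categorical
predictors are presented to the imputation trees as ordered integer
codes, because exhaustive subset search over many-level factors is
exponential in the tree backend; sorted codes keep country-qualified
categories contiguous, so axis splits can still isolate them.

## The portfolio simulator

Because real multi-country experience data are confidential, the package
ships a simulator with known ground truth. `default_study_config()`
reproduces the *shape* of a realistic eight-country study — per-country
group counts, exposure magnitudes, observation-year ranges, and
missingness patterns are hard-coded template constants, scalable by a
single `scale` factor. The generative model is:

* Gompertz age baseline $\mu_0(a) = a_0 e^{b_0 a}$ with $a_0 = 2 \times
  10^{-5}$, $b_0 = 0.09$, ages 25–70 — insured-population magnitudes;
* multiplicative global effects (gender log rate-ratio 0.45, mild
  calendar-year and duration trends, sum-band gradient);
* per-country level shifts and per-country *multipliers* on shared local
  effect templates, so local features matter by different amounts in
  different countries, including sign flips and interactions in two
  countries;
* local categorical values are prefixed with the country id (`"7:r1"`),
  mirroring the reality that local codes are not comparable across
  countries;
* lognormal exposures per record, then $D \sim \text{Poisson}(\mu E)$,
  then masking: missingness is applied *after* truth computation, so the
  stored ground-truth rates are unaffected by it, and one country lacks
  one local feature entirely.

The simulator returns the truth alongside the table, enabling the
oracle diagnostics (`rmse` against true rates, the true-model
log-likelihood bound) that real data cannot provide. What it does *not*
emulate: reporting lags, duplicate policies, exposure measurement error,
non-Poisson overdispersion, or secular mortality shocks — the noise
model is exactly Poisson, which is also what the estimators assume.

## Problem sizes and numerical choices

The package's own study scale (`scale = 0.01`, roughly 2,000 grouped
records and 350 deaths across eight countries) is chosen so the full
four-strategy benchmark runs in about a minute and a half on one CPU;
the simulator scales linearly to the full template (about 190,000
groups) for larger experiments. Model settings for the scaled-down study
are regularised accordingly (global: 150 trees, 8 leaves,
`min_deaths_per_leaf = 10`; local: 30 trees at rate 0.05, 4 leaves).

Numerical conventions worth knowing:

* predicted rates are floored at $10^{-12}$ before logs;
* `poisson_loglik` omits the $\log D!$ term (model-independent), so
  values are comparable across models on the same data, not across data;
* `rmse` is root-*mean*-square;
* all stochastic stages (simulation, fold assignment, encoder folds,
  bootstraps) draw sub-seeds deterministically from a master seed via a
  string-keyed hash, so component seeds never collide and every result
  is bit-reproducible end to end.

## Limitations

* The local step shrinks by under-convergence, not by an explicit prior:
  the pooling strength is a hyperparameter (learning budget), not
  estimated from the between-country variance.
* Leaf constraints are enforced in expected-death units only;
  exposure-based constraints are approximated through the portfolio
  rate.
* Tree-based predictions are step functions of age; they do not inherit
  the smoothness of the underlying Gompertz curve, and the age-smoothness
  diagnostic reflects this (fitted models score visibly rougher than the
  true log-linear curve regardless of data volume).
* Final-fit encodings trade a small amount of self-fit for exact
  calibration, as discussed above.
* The simulator's Poisson noise model matches the estimators'
  assumption; real experience data are typically overdispersed.
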