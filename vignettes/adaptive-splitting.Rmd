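---
title: "Adaptive discovery/validation splitting: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive discovery/validation splitting: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A prospective predictive-modeling study has a fixed *sample-size budget*
`n_total`: the total number of participants that can be measured. Some of
them must be spent on *discovery* (training and tuning the model), the rest
on *external validation* of the finalized, publicly deposited ("registered")
model. Fixed allocations — half-split, the 80:20 Pareto split, 90:10 — are
blind to how the model's performance actually grows with training data. If
the learning curve is flat and low, validation needs many observations to be
conclusive; if the curve keeps rising, every additional discovery
observation buys real performance and a small validation sample suffices; if
the curve plateaus early, discovery should stop and the remaining budget is
better spent validating.

`adasplit` implements a stopping rule that is evaluated repeatedly while
data accrue. Discovery ends — and the model is frozen — at the first
acquisition step where the rule returns `TRUE`.

## The stopping rule

With `n_act` observations acquired so far, the rule is the composition

```
stop  =  Min-rule  AND  ( Max-rule  OR  Performance-rule  OR  Power-rule )
```

where

* **Min-rule**: `n_act >= t_min`. A hard floor; below it performance and
  power estimates are too unreliable to act on. Default
  `t_min = ceiling(n_total / 3)`.
* **Max-rule**: `n_act >= n_total - v_min`. A hard ceiling that reserves at
  least `v_min` observations (default 12) for validation and guarantees that
  any replay terminates.
* **Performance-rule**: `s_hat_total - s_act <= s_min`. `s_act` is the
  current cross-validated performance (the last point of the bootstrapped
  learning curve); `s_hat_total` is the tangent extrapolation of that curve
  to the full budget. When even this optimistic forecast promises a gain of
  at most `s_min` (default 0, i.e. the rule only fires on flat or declining
  curves), continuing discovery is pointless.
* **Power-rule**: `POW_alpha(s_act, n_val) <= v_pow` with
  `n_val = n_total - n_act`. The estimated probability that a validation
  sample consisting of the entire remaining budget would reject the null of
  zero predictive performance. Power shrinks as the remaining sample
  shrinks, so the rule fires at the first step where waiting any longer
  would leave the external validation under-powered (default target
  `v_pow = 0.8` at `alpha = 0.05`).

Setting `t_min + v_min = n_total` collapses the whole machinery into a
predefined fixed split; the replay harness exploits this for an exact
equivalence test against `run_fixed()`.

The published description states the composition as the formula above, but
the surrounding prose sequences the sub-rules differently (performance gated
on the minimum rule, power gated on the performance rule). The formula is
implemented as normative; the decision record retains all four booleans so
any alternative gating can be audited after the fact.

## Reference estimators

The rule is evaluated against ridge regression (regression tasks) or
L2-regularized logistic regression (classification). The penalty is tuned by
k-fold cross-validation over the grid `{0.1, 1, 10}` (classical
`loss + penalty * ||beta||^2` scale; the glmnet backend receives
`penalty / n`). Choices where the published description is silent:

* Features are standardized (center and scale) with constants learned from
  the training partition only — regularized linear models need comparable
  feature scales, and re-learning the constants per fold prevents leakage.
* Classification folds are stratified; regression folds are contiguous
  blocks of a seeded shuffle. `k = 5` by default, reduced automatically when
  classes are small; every training partition must retain at least two
  members of each class, and when even that is impossible the tuner falls
  back to the most regularized grid value (the same preference as the
  tie-break) fitted on all rows.
* Ties in mean CV score go to the largest penalty: when the data cannot
  distinguish penalties, prefer the simpler model.
* Classification predicts hard labels at linear score 0 (probability 0.5).
* All scorers are higher-is-better (accuracy; negative mean absolute error;
  explained variance) so the rule's comparisons and the tangent
  extrapolation are metric-agnostic.

`cv_predict()` produces out-of-fold predictions with the penalty re-tuned
inside every outer training fold (nested CV), so each observation is
predicted by a model that never saw it. These pairs feed both the learning
curve and the power analysis.

## Bootstrapped learning curve and tangent extrapolation

For each size `m` on a grid, `n_boot` subsamples are drawn **without**
replacement (stratified for classification, class ratio preserved to one
observation), each scored by nested CV; the per-size mean is the curve and
the 2.5/97.5 percentiles form its band. Internals not fixed by the published
description, chosen here once:

* grid: up to 5 evenly spaced sizes from `max(12, smallest CV-feasible
  size)` to `n_act` — enough points for a stable finite difference at
  tolerable cost;
* `n_boot = 50` by default; the aggregation is the mean (the description
  calls the quantity a bootstrapped score without naming the statistic);
* the percentile band needs a few dozen draws before its 2.5/97.5 quantiles
  are resolved; with 10 draws it is truncated toward the sample range by
  construction. Width stability should therefore be judged from roughly 50
  draws upward, which is how the test suite asserts it.

`s_hat_total` extends the last curve segment linearly to `n_total`. For
concave (saturating) learning curves this is an upper bound on what the full
budget can deliver, which is exactly the property the Performance-rule
needs: if even an optimistic bound shows no relevant gain, stop. A negative
last slope is retained so a declining curve can trigger the rule at
`s_min = 0`. The result is clipped at the scorer's attainable upper bound.

## Permutation test and validation power

Significance of predictive performance is assessed non-parametrically: the
truth vector is permuted against the fixed predictions, and
`p = (1 + #{s_perm >= s_obs}) / (n_perm + 1)` (add-one convention, so p is
never zero; ties count toward the null). For `n <= 7` all `n!` permutations
are enumerated instead of sampled. The confirmatory external validation uses
5,000 permutations; power estimation inside the rule uses 500 by default,
since only the rejection fraction matters there.

Power at a candidate validation size `n_val` is estimated by resampling the
discovery-phase out-of-fold pairs **with** replacement at size `n_val`
(`n_boot = 100` by default) and counting resamples whose permutation test
rejects at `alpha`. The body of this procedure is not printed in the
published description; resampling pairs at the target size is the natural
reading and is the normative choice here. Sizes below 3 return power 0 — no
testable sample, no rejection. Two calibration facts, both verified by the
test suite, are worth knowing:

* conditional on one dataset, the estimate tracks that dataset's accidental
  truth/prediction association; the "power equals alpha under the null"
  property holds marginally over datasets, and that is how it is tested;
* power is monotone in `n_val` and in the underlying effect size only up to
  Monte-Carlo noise; tests allow a 0.05 tolerance on monotonicity.

## Replay harness

`replay_adaptive()` simulates prospective acquisition on a finite dataset:
draw `n_total` rows without replacement (the acquisition order), evaluate
the rule at 10% of the budget and then every 5% (rounded up, clipped to the
Max-rule cap; both fractions configurable), and on stopping fit the final
model on all discovery rows, then validate on the remaining rows with the
5,000-permutation test. Seeds form a tree — master seed, per-repetition
seed, per-component seed — so any cell of a large comparison is re-runnable
in isolation, and fixed-split and adaptive replays share the same budget
draw under a shared seed (paired comparisons).
`compare_strategies()` aggregates means, percentile intervals and
conclusive-validation counts over repetitions (default 100) and budgets.

## Synthetic data

Generators exist so every stage is testable without downloads. Gaussian
designs give closed-form control: regression targets have population
R-squared equal to `target_signal`; classification classes are unit-variance
Gaussians separated by `d`, with Bayes accuracy `pnorm(d/2)` for balanced
classes. Three archetypes emulate canonical learning-curve shapes via the
structure of the signal, with parameters fixed once from pilot curve
measurements (flat: a single weak feature, separation 0.8 among 2 features;
rising: separation 3 spread over 40 equally weak features, so accuracy keeps
climbing while many small coefficients are estimated; plateau: a single
dominant feature, separation 3 among 6, saturating by roughly 60
observations). What they deliberately do not emulate: feature correlation
structure of real biomedical data, site/batch effects, label noise,
covariate shift. Passing tests on these generators demonstrate the
*mechanics* of the rule (termination, floors, orderings, calibration), not
performance on any particular real dataset.

## Packaged example data

`inst/extdata/bcw_subsample.csv` is a 250-row stratified subsample (class
ratio preserved, features rounded to 4 significant digits) of the public
Breast Cancer Wisconsin diagnostic dataset: 30 morphological features of
cell nuclei from fine-needle aspirates, with a benign/malignant label. It
keeps the package self-contained for a realistic classification replay.

## Problem sizes used by the tests and the acceptance script

Simulation sizes are scaled to what the checks need, not more: replays in
the test suite use 3-fold CV, learning-curve bootstraps of 6–20 draws,
power bootstraps of 20–50 draws with 49–199 permutations, and 199–999
confirmatory permutations; the archetype comparison runs 25 paired replays
at budget 300 on a coarsened (10%) schedule, and the Breast Cancer replay 8
repetitions per budget. The acceptance script mirrors these settings with 6
repetitions per budget. Calibration checks (type-I error, null power) use
500–1,000 Monte-Carlo replicates against 99% binomial bands.

## Known limitations

* The tangent extrapolation is a first-order device: on noisy curves its
  sign flips easily, so with `s_min = 0` the Performance-rule can fire on a
  curve that is still slowly rising. Larger `n_boot` and more grid points
  stabilize it at quadratic cost.
* Bootstrapped power at `n_val` close to `n_act` reuses pairs and slightly
  overstates evidence (duplicate aligned pairs look like signal to the
  permutation test); at `alpha = 0.05` the measured inflation is on the
  order of one percentage point.
* Estimators are the two reference linear models; the module contract
  (fit/predict/score with internal tuning) is the extension point for
  anything else.
* The rule assumes observations arrive in exchangeable order; drifting
  acquisition (e.g. site changes mid-study) violates the premise of both the
  learning curve and the power analysis.
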