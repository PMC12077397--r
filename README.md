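# adasplit

Adaptive splitting of a fixed sample-size budget between model discovery
and external validation, for prospective predictive-modeling studies.

## The problem

A study that wants to both *build* a predictive model and *externally
validate* it on guaranteed-unseen data must decide how many of its
`n_total` participants go to discovery and how many to validation. Fixed
recipes (50:50, the 80:20 "Pareto" split, 90:10) ignore the shape of the
model's learning curve and routinely either waste discovery data on a
plateaued model or leave the validation under-powered and inconclusive.

`adasplit` implements an adaptive design: while data accrue, a stopping
rule `S` is evaluated on the `n_act` observations acquired so far, and the
discovery phase ends at the first acquisition step where

```
S  =  Min-rule  AND  ( Max-rule  OR  Performance-rule  OR  Power-rule )

Min-rule:          n_act >= t_min
Max-rule:          n_act >= n_total - v_min
Performance-rule:  s_hat_total - s_act <= s_min
Power-rule:        POW_alpha(s_act, n_total - n_act) <= v_pow
```

`s_act` is the bootstrapped nested-CV performance on the acquired data,
`s_hat_total` its tangent-line extrapolation to the full budget, and
`POW_alpha(s, n)` the bootstrapped power of a permutation test on a
prospective validation sample of size `n`. At stop, the model is finalized
on all discovery rows and can be deposited as a checksummed
"registered model" bundle before the validation data are acquired.

The package provides the stopping rule and its audit trail
(`evaluate_stopping`), the reference estimators — ridge and L2-regularized
logistic regression with nested cross-validated tuning (`fit_tuned`,
`cv_predict`) — the bootstrapped learning curve (`bootstrap_learning_curve`,
`extrapolate_tangent`), the permutation test and validation power curve
(`permutation_test`, `estimate_power`, `compute_power_curve`), a replay
harness comparing adaptive against fixed splits (`replay_adaptive`,
`run_fixed`, `compare_strategies`), synthetic-data generators with
controllable learning-curve shapes (`make_regression`,
`make_classification`, `make_archetype`), model freezing with SHA-256
verification (`freeze_model`, `verify_bundle`, `load_frozen_model`), and a
command-line interface (`adasplit_cli`, script in `inst/cli/`).

## Worked example

A 250-row subsample of the Breast Cancer Wisconsin diagnostic dataset (30
cell-nucleus features, benign/malignant label) ships with the package.
Replay a prospective study with a budget of 113 participants:

```r
library(adasplit)

bcw <- read_dataset(system.file("extdata", "bcw_subsample.csv",
                                package = "adasplit"),
                    target_column = "diagnosis")
bcw
#> <adasplit_dataset> 250 obs x 30 features, task: classification
#>   classes: B=157, M=93

out <- replay_adaptive(bcw, n_total = 113, seed = 7,
                       lc_boot = 20, pow_boot = 50, pow_perm = 199)
out
#> <split_outcome> adaptive: discovery 42 / validation 71 (of 113)
#>   discovery score 0.9226 | external score 0.9577 (p = 0.0002)

out$trajectory[[length(out$trajectory)]]
#> <stop_decision> n_act=42 / n_total=113: STOP
#>   min=TRUE max=FALSE performance=TRUE power=FALSE
#>   s_act=0.9226  s_hat_total=0.8754  power@71=1.000
```

Reading the decision: at `n_act = 42` the Min-rule floor
(`t_min = ceiling(113/3) = 38`) is satisfied; the bootstrapped learning
curve gives a cross-validated accuracy of 0.923, and its tangent
extrapolation to the full budget promises no further gain
(`s_hat_total = 0.875 <= s_act`), so the Performance-rule fires. The
remaining 71 participants form the external validation sample, on which
the frozen model reaches accuracy 0.958 with permutation p = 0.0002
(5,000 permutations) — a conclusive external validation. On a dataset
whose learning curve were still climbing, the rule would instead have kept
acquiring discovery data until the estimated validation power of the
remaining budget dropped to the target `v_pow = 0.8` or the Max-rule
reserve of `v_min = 12` was reached.

The same machinery is available from the shell:

```sh
Rscript inst/cli/adasplit generate --archetype plateau --n 300 --seed 1 --out demo.csv
Rscript inst/cli/adasplit check-stop --data demo.csv --n-total 300 --seed 1 --out decision.json
Rscript inst/cli/adasplit freeze --data demo.csv --seed 1 --out model.json
Rscript inst/cli/adasplit verify --bundle model.json
```

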