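#' Stopping-rule parameters
#'
#' The adaptive stopping rule is configured by five parameters:
#' * `t_min` — minimum discovery (training) sample size; the rule can
#'   never stop before `n_act >= t_min`.
#' * `v_min` — minimum external validation sample size; the rule always
#'   stops once only `v_min` observations of the budget remain
#'   (default 12).
#' * `s_min` — smallest predictive performance gain of interest, on the
#'   scorer's scale; the default 0 effectively switches the
#'   performance rule off except on flat or declining learning curves.
#' * `v_pow` — target power of the external validation (default 0.8).
#' * `alpha` — significance level of the validation permutation test
#'   (default 0.05).
#'
#' Setting `t_min + v_min = n_total` reduces the adaptive rule to a
#' predefined fixed split.
#'
#' @param t_min integer `>= 0`; `NULL` lets the replay harness fill in
#'   its default `ceiling(n_total / 3)`.
#' @param v_min integer `>= 0`.
#' @param s_min real.
#' @param v_pow real in (0, 1).
#' @param alpha real in (0, 1).
#' @return a `rule_params` list.
#' @export
rule_params <- function(t_min = NULL, v_min = 12, s_min = 0,
                        v_pow = 0.8, alpha = 0.05) {
  if (!is.null(t_min) && t_min < 0) stop("t_min must be non-negative")
  if (v_min < 0) stop("v_min must be non-negative")
  if (v_pow <= 0 || v_pow >= 1) stop("v_pow must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("invalid alpha")
  structure(
    list(t_min = if (is.null(t_min)) NULL else as.integer(t_min),
         v_min = as.integer(v_min), s_min = s_min,
         v_pow = v_pow, alpha = alpha),
    class = "rule_params"
  )
}

#' Acquisition state
#'
#' @param n_act observations acquired so far (`> 0`).
#' @param n_total the total sample-size budget (`>= n_act`).
#' @return an `acquisition_state` list.
#' @export
acquisition_state <- function(n_act, n_total) {
  if (n_act <= 0) stop("n_act must be positive")
  if (n_total < n_act) stop("n_total must be at least n_act")
  structure(list(n_act = as.integer(n_act), n_total = as.integer(n_total)),
            class = "acquisition_state")
}

#' Min-rule: has the discovery floor been reached?
#'
#' `TRUE` when `n_act >= t_min`. Gates the whole stopping rule, keeping
#' acquisition going while performance and power estimates are still
#' unreliable.
#'
#' @param state an [acquisition_state()].
#' @param params a [rule_params()].
#' @return logical.
#' @export
min_rule <- function(state, params) state$n_act >= params$t_min

#' Max-rule: is only the validation floor left?
#'
#' `TRUE` when `n_act >= n_total - v_min`, i.e. continuing discovery
#' would eat into the guaranteed minimum validation sample. This bound
#' forces termination of any replay.
#'
#' @inheritParams min_rule
#' @return logical.
#' @export
max_rule <- function(state, params) state$n_act >= state$n_total - params$v_min

#' Performance-rule: is the expected gain negligible?
#'
#' `TRUE` when the tangent-extrapolated full-budget score exceeds the
#' current score by at most `s_min` — the learning curve has plateaued
#' (or declines), so further discovery data promise no relevant gain.
#'
#' @param s_hat_total extrapolated full-budget score ([extrapolate_tangent()]).
#' @param s_act current score ([actual_score()]).
#' @param params a [rule_params()].
#' @return logical; `NA` inputs yield `FALSE` (no plateau claim without
#'   an extrapolation).
#' @export
performance_rule <- function(s_hat_total, s_act, params) {
  if (is.na(s_hat_total) || is.na(s_act)) return(FALSE)
  (s_hat_total - s_act) <= params$s_min
}

#' Power-rule: would waiting longer under-power the validation?
#'
#' `TRUE` when the estimated power of a validation sample consisting of
#' the entire remaining budget has fallen to `v_pow` or below. Because
#' power shrinks as the remaining sample shrinks, the rule fires at the
#' first acquisition step where postponing the stop any further would
#' leave the external validation under-powered.
#'
#' @param power_at_remaining estimated power at `n_val = n_total - n_act`.
#' @param params a [rule_params()].
#' @return logical.
#' @export
power_rule <- function(power_at_remaining, params) {
  stopifnot(power_at_remaining >= 0, power_at_remaining <= 1)
  power_at_remaining <= params$v_pow
}

#' Compose the four sub-rules into the stopping decision
#'
#' The discovery phase stops iff
#' `Min-rule AND (Max-rule OR Performance-rule OR Power-rule)`.
#'
#' @param min_rule,max_rule,performance_rule,power_rule logicals.
#' @return logical.
#' @export
combine_rules <- function(min_rule, max_rule, performance_rule, power_rule) {
  min_rule & (max_rule | performance_rule | power_rule)
}

#' Evaluate the adaptive stopping rule on acquired data
#'
#' Runs the full decision pipeline at one acquisition step: bootstrapped
#' learning curve on the acquired data, current score `s_act`, tangent
#' extrapolation to the full budget, nested-CV out-of-fold predictions,
#' estimated power of a validation sample holding the whole remaining
#' budget, and the four sub-rules composed by [combine_rules()]. Every
#' intermediate quantity is recorded in the returned decision for audit.
#'
#' @param dataset_act acquired data; must have exactly `state$n_act` rows.
#' @param spec a [model_spec()]; default per task.
#' @param state an [acquisition_state()].
#' @param params a [rule_params()] with non-`NULL` `t_min`.
#' @param seed integer seed.
#' @param lc_grid,lc_boot learning-curve grid and bootstrap count
#'   (defaults as in [bootstrap_learning_curve()]).
#' @param pow_boot,pow_perm bootstrap resamples and permutations for the
#'   power estimate (defaults as in [estimate_power()]).
#' @return a `stop_decision`: `stop` plus the four sub-rule booleans,
#'   `s_act`, `s_hat_total`, `power_at_remaining`, `n_val_if_stop`,
#'   `state`, `params`, `seed`, `flags`, and diagnostics (`curve`,
#'   `prediction_sample`). When `n_act` is below the minimum evaluable
#'   size for cross-validation the decision is `stop = FALSE` with flag
#'   `"below minimum evaluable size"`.
#' @export
evaluate_stopping <- function(dataset_act, spec = NULL, state, params,
                              seed = 1, lc_grid = NULL, lc_boot = 50,
                              pow_boot = 100, pow_perm = 500) {
  stopifnot(inherits(dataset_act, "adasplit_dataset"),
            inherits(state, "acquisition_state"),
            inherits(params, "rule_params"))
  if (is.null(params$t_min)) stop("t_min must be set (see rule_params)")
  if (dataset_act$n != state$n_act) {
    stop("dataset_act must have exactly n_act rows")
  }
  if (is.null(spec)) spec <- default_spec(dataset_act)
  n_val <- state$n_total - state$n_act

  feasible <- tryCatch({
    make_folds(dataset_act$target, dataset_act$task, spec$cv_folds,
               1L)
    TRUE
  }, error = function(e) FALSE)
  if (!feasible) {
    # hard thresholds still apply: the Max-rule bound must terminate a
    # replay even when the sample cannot support cross-validation
    return(new_stop_decision(
      stop = min_rule(state, params) && max_rule(state, params),
      min_r = min_rule(state, params), max_r = max_rule(state, params),
      perf_r = FALSE, pow_r = FALSE, s_act = NA_real_, s_hat = NA_real_,
      power = NA_real_, state = state, params = params, seed = seed,
      flags = "below minimum evaluable size", curve = NULL, ps = NULL))
  }

  curve <- bootstrap_learning_curve(dataset_act, spec, grid = lc_grid,
                                    n_boot = lc_boot,
                                    seed = child_seed(seed, .SEED_CURVE))
  s_act <- actual_score(curve)
  s_hat <- if (length(curve$sizes) >= 2) {
    extrapolate_tangent(curve, state$n_total)
  } else NA_real_

  ps <- cv_predict(dataset_act, spec, child_seed(seed, .SEED_PRED))
  power <- estimate_power(ps, n_val, alpha = params$alpha,
                          n_boot = pow_boot, n_perm = pow_perm,
                          seed = child_seed(seed, .SEED_POWER))

  min_r <- min_rule(state, params)
  max_r <- max_rule(state, params)
  perf_r <- performance_rule(s_hat, s_act, params)
  pow_r <- power_rule(power, params)
  flags <- character(0)
  if (is.na(s_hat)) flags <- c(flags, "single-point learning curve")

  new_stop_decision(
    stop = combine_rules(min_r, max_r, perf_r, pow_r),
    min_r = min_r, max_r = max_r, perf_r = perf_r, pow_r = pow_r,
    s_act = s_act, s_hat = s_hat, power = power,
    state = state, params = params, seed = seed, flags = flags,
    curve = curve, ps = ps)
}

new_stop_decision <- function(stop, min_r, max_r, perf_r, pow_r, s_act,
                              s_hat, power, state, params, seed, flags,
                              curve, ps) {
  structure(
    list(stop = stop, min_rule = min_r, max_rule = max_r,
         performance_rule = perf_r, power_rule = pow_r,
         s_act = s_act, s_hat_total = s_hat, power_at_remaining = power,
         n_act = state$n_act, n_total = state$n_total,
         n_val_if_stop = state$n_total - state$n_act,
         params = unclass(params), seed = seed, flags = flags,
         curve = curve, prediction_sample = ps),
    class = "stop_decision"
  )
}

#' @export
print.stop_decision <- function(x, ...) {
  cat(sprintf("<stop_decision> n_act=%d / n_total=%d: %s\n",
              x$n_act, x$n_total, if (x$stop) "STOP" else "continue"))
  cat(sprintf("  min=%s max=%s performance=%s power=%s\n",
              x$min_rule, x$max_rule, x$performance_rule, x$power_rule))
  cat(sprintf("  s_act=%.4f  s_hat_total=%.4f  power@%d=%.3f\n",
              x$s_act, x$s_hat_total, x$n_val_if_stop,
              x$power_at_remaining))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a stopping decision to JSON
#'
#' Writes all sub-rule booleans, scores, power, parameters and the seed
#' — the audit trail to attach to a preregistration.
#'
#' @param decision a `stop_decision`.
#' @param path output path, or `NULL` to return the JSON string.
#' @return the path (invisibly) or a JSON string.
#' @export
decision_json <- function(decision, path = NULL) {
  payload <- decision[c("stop", "min_rule", "max_rule", "performance_rule",
                        "power_rule", "s_act", "s_hat_total",
                        "power_at_remaining", "n_act", "n_total",
                        "n_val_if_stop", "params", "seed", "flags")]
  if (!is.null(decision$curve)) {
    payload$learning_curve <- as.data.frame(decision$curve)
  }
  if (is.null(path)) {
    as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
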