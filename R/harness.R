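#' Acquisition schedule
#'
#' The replay harness evaluates the stopping rule on a schedule of
#' acquisition steps: starting at `start_fraction` of the budget and
#' growing in increments of `step_fraction` (both rounded up), clipped
#' to the Max-rule bound `n_total - v_min`.
#'
#' @param start_fraction first evaluation point as a fraction of
#'   `n_total` (default 0.10).
#' @param step_fraction increment as a fraction of `n_total`
#'   (default 0.05).
#' @return an `acquisition_schedule` list.
#' @export
acquisition_schedule <- function(start_fraction = 0.10, step_fraction = 0.05) {
  if (start_fraction <= 0 || start_fraction > 1) stop("invalid start_fraction")
  if (step_fraction <= 0 || step_fraction > 1) stop("invalid step_fraction")
  structure(list(start_fraction = start_fraction,
                 step_fraction = step_fraction),
            class = "acquisition_schedule")
}

schedule_steps <- function(schedule, n_total, v_min) {
  cap <- n_total - v_min
  n0 <- ceiling(schedule$start_fraction * n_total)
  by <- ceiling(schedule$step_fraction * n_total)
  steps <- seq(min(n0, cap), cap, by = by)
  if (steps[length(steps)] < cap) steps <- c(steps, cap)
  as.integer(steps)
}

# shared budget draw: identical across strategies for a given seed so
# adaptive and fixed splits are compared on the same simulated study
draw_budget_rows <- function(dataset, n_total, seed) {
  if (n_total > dataset$n) stop("budget exceeds available data")
  with_seed(child_seed(seed, .SEED_DRAW), sample.int(dataset$n, n_total))
}

#' Replay a prospective study with the adaptive stopping rule
#'
#' Simulates prospective data acquisition on a finite dataset: draws
#' `n_total` rows without replacement (the acquisition order), grows the
#' acquired sample along the schedule, and evaluates
#' [evaluate_stopping()] at each step. When the rule fires, the model is
#' finalized on the discovery rows ([fit_tuned()]) and externally
#' validated on all remaining rows with a confirmatory permutation test.
#'
#' @param dataset pool of available observations (`>= n_total` rows).
#' @param n_total sample-size budget.
#' @param params a [rule_params()]; a `NULL` `t_min` is filled with
#'   `ceiling(n_total / 3)`. Requires `t_min + v_min <= n_total`.
#' @param spec a [model_spec()]; default per task.
#' @param schedule an [acquisition_schedule()].
#' @param seed integer master seed for this replayed study.
#' @param lc_grid,lc_boot,pow_boot,pow_perm passed to
#'   [evaluate_stopping()].
#' @param final_perm permutations of the confirmatory external test
#'   (default 5000).
#' @return a `split_outcome`: `strategy`, `n_discovery`,
#'   `n_validation`, `discovery_score` (bootstrapped CV score at stop),
#'   `external_score`, `external_p`, `trajectory` (list of
#'   `stop_decision`s), `model`, `rows` (the drawn acquisition order),
#'   `params`, `seed`.
#' @export
replay_adaptive <- function(dataset, n_total, params = NULL, spec = NULL,
                            schedule = acquisition_schedule(), seed = 1,
                            lc_grid = NULL, lc_boot = 50, pow_boot = 100,
                            pow_perm = 500, final_perm = 5000) {
  stopifnot(inherits(dataset, "adasplit_dataset"))
  if (is.null(params)) params <- rule_params()
  if (is.null(params$t_min)) params$t_min <- as.integer(ceiling(n_total / 3))
  if (params$t_min + params$v_min > n_total) {
    stop("t_min + v_min exceeds the sample size budget")
  }
  if (is.null(spec)) spec <- default_spec(dataset)
  rows <- draw_budget_rows(dataset, n_total, seed)

  steps <- schedule_steps(schedule, n_total, params$v_min)
  trajectory <- list()
  n_stop <- NA_integer_
  for (i in seq_along(steps)) {
    m <- steps[i]
    dec <- evaluate_stopping(
      ds_slice(dataset, rows[seq_len(m)]), spec,
      acquisition_state(m, n_total), params,
      seed = child_seed(seed, .SEED_STEP, i),
      lc_grid = lc_grid, lc_boot = lc_boot,
      pow_boot = pow_boot, pow_perm = pow_perm)
    trajectory[[i]] <- dec
    if (dec$stop) { n_stop <- m; break }
  }
  stopifnot(!is.na(n_stop)) # Max-rule guarantees termination at the cap

  finalize_outcome(dataset, rows, n_stop, spec, seed,
                   strategy = "adaptive", final_perm = final_perm,
                   params = params, trajectory = trajectory,
                   discovery_score = trajectory[[length(trajectory)]]$s_act)
}

#' Replay a prospective study with a fixed split ratio
#'
#' Uses the first `ceiling(ratio * n_total)` rows of the same seeded
#' budget draw as [replay_adaptive()] for discovery and the rest for
#' external validation, with the identical final fit and confirmatory
#' test — so outcomes are directly paired with the adaptive strategy
#' under a shared seed.
#'
#' @inheritParams replay_adaptive
#' @param ratio discovery fraction in (0, 1): 0.5 (half split), 0.8
#'   (Pareto split), 0.9, ...
#' @return a `split_outcome` (see [replay_adaptive()]); its
#'   `discovery_score` is the nested-CV score on the discovery rows.
#' @export
run_fixed <- function(dataset, n_total, ratio, spec = NULL, seed = 1,
                      final_perm = 5000) {
  stopifnot(inherits(dataset, "adasplit_dataset"))
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  if (is.null(spec)) spec <- default_spec(dataset)
  rows <- draw_budget_rows(dataset, n_total, seed)
  n_disc <- as.integer(ceiling(ratio * n_total))
  if (n_disc >= n_total) stop("empty validation set")
  disc_ps <- cv_predict(ds_slice(dataset, rows[seq_len(n_disc)]), spec,
                        child_seed(seed, .SEED_DISC))
  finalize_outcome(dataset, rows, n_disc, spec, seed,
                   strategy = sprintf("fixed:%g", ratio),
                   final_perm = final_perm, params = NULL,
                   trajectory = NULL,
                   discovery_score = score(disc_ps$truth, disc_ps$prediction,
                                           spec$scorer_id))
}

finalize_outcome <- function(dataset, rows, n_disc, spec, seed, strategy,
                             final_perm, params, trajectory,
                             discovery_score) {
  n_total <- length(rows)
  disc <- ds_slice(dataset, rows[seq_len(n_disc)])
  val <- ds_slice(dataset, rows[(n_disc + 1):n_total])
  model <- fit_tuned(disc, spec, child_seed(seed, .SEED_FIT))
  ev <- external_validate(model, val, spec$scorer_id, n_perm = final_perm,
                          seed = child_seed(seed, .SEED_VAL))
  structure(
    list(strategy = strategy, n_total = as.integer(n_total),
         n_discovery = as.integer(n_disc),
         n_validation = as.integer(n_total - n_disc),
         discovery_score = discovery_score,
         external_score = ev$score, external_p = ev$p,
         trajectory = trajectory, model = model, rows = rows,
         params = params, seed = seed),
    class = "split_outcome"
  )
}

#' Externally validate a frozen model
#'
#' Scores a finalized model on validation data it has never seen and
#' attaches a permutation p-value. The model is applied as-is — no
#' refitting, no re-learned preprocessing.
#'
#' @param model an `adasplit_model` (frozen before seeing these rows).
#' @param validation an `adasplit_dataset`.
#' @param scorer scorer id or object.
#' @param n_perm confirmatory permutations (default 5000).
#' @param seed integer seed.
#' @return list with `score` and `p`.
#' @export
external_validate <- function(model, validation, scorer, n_perm = 5000,
                              seed = 1) {
  stopifnot(inherits(model, "adasplit_model"))
  if (validation$n < 1) stop("empty validation set")
  pred <- predict(model, validation$features)
  s <- score(validation$target, pred, scorer)
  p <- permutation_test(validation$target, pred, scorer, n_perm = n_perm,
                        seed = seed)
  list(score = s, p = p)
}

#' @export
print.split_outcome <- function(x, ...) {
  cat(sprintf(
    "<split_outcome> %s: discovery %d / validation %d (of %d)\n",
    x$strategy, x$n_discovery, x$n_validation, x$n_total))
  cat(sprintf("  discovery score %.4f | external score %.4f (p = %.4g)\n",
              x$discovery_score, x$external_score, x$external_p))
  invisible(x)
}

parse_strategy <- function(s) {
  if (identical(s, "adaptive")) return(list(kind = "adaptive"))
  if (grepl("^fixed:", s)) {
    r <- as.numeric(sub("^fixed:", "", s))
    if (is.finite(r) && r > 0 && r < 1) return(list(kind = "fixed", ratio = r))
  }
  stop("unknown strategy: ", s, " (use 'adaptive' or 'fixed:<ratio>')")
}

#' Compare splitting strategies over budgets and repetitions
#'
#' Runs every (budget, strategy, repetition) cell of a replay
#' experiment. Repetitions share seeds across strategies (paired
#' comparisons on identical budget draws) but are independent across
#' repetitions and budgets. Summaries report means and 2.5/97.5
#' percentile intervals of the external score, external p-value and
#' discovery fraction, plus the count of conclusive validations
#' (`p < alpha`).
#'
#' @inheritParams replay_adaptive
#' @param budgets integer vector of total sample sizes (each `<=`
#'   dataset rows).
#' @param strategies character vector: `"adaptive"` and/or
#'   `"fixed:<ratio>"` entries (default adaptive vs half, Pareto and
#'   90:10 splits).
#' @param reps repetitions per cell (default 100).
#' @return a `strategy_comparison`: `runs` (tibble of all outcomes) and
#'   `summary` (tibble, one row per budget x strategy).
#' @export
compare_strategies <- function(dataset, budgets,
                               strategies = c("adaptive", "fixed:0.5",
                                              "fixed:0.8", "fixed:0.9"),
                               reps = 100, params = NULL, spec = NULL,
                               schedule = acquisition_schedule(), seed = 1,
                               lc_grid = NULL, lc_boot = 50, pow_boot = 100,
                               pow_perm = 500, final_perm = 5000) {
  stopifnot(inherits(dataset, "adasplit_dataset"))
  if (max(budgets) > dataset$n) stop("budget exceeds available data")
  alpha <- if (is.null(params)) 0.05 else params$alpha
  rows <- list()
  for (bi in seq_along(budgets)) {
    b <- budgets[bi]
    for (r in seq_len(reps)) {
      rep_seed <- child_seed(seed, bi * 1000L, r)
      for (s in strategies) {
        st <- parse_strategy(s)
        out <- if (st$kind == "adaptive") {
          replay_adaptive(dataset, b, params = params, spec = spec,
                          schedule = schedule, seed = rep_seed,
                          lc_grid = lc_grid, lc_boot = lc_boot,
                          pow_boot = pow_boot, pow_perm = pow_perm,
                          final_perm = final_perm)
        } else {
          run_fixed(dataset, b, st$ratio, spec = spec, seed = rep_seed,
                    final_perm = final_perm)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          budget = b, strategy = s, rep = r, seed = rep_seed,
          n_discovery = out$n_discovery, n_validation = out$n_validation,
          discovery_fraction = out$n_discovery / b,
          discovery_score = out$discovery_score,
          external_score = out$external_score, external_p = out$external_p)
      }
    }
  }
  runs <- dplyr::bind_rows(rows)
  q <- function(x, p) stats::quantile(x, p, names = FALSE)
  summary <- runs |>
    dplyr::group_by(.data$budget, .data$strategy) |>
    dplyr::summarise(
      reps = dplyr::n(),
      conclusive = sum(.data$external_p < alpha),
      discovery_fraction_lo = q(.data$discovery_fraction, 0.025),
      discovery_fraction_hi = q(.data$discovery_fraction, 0.975),
      external_score_lo = q(.data$external_score, 0.025),
      external_score_hi = q(.data$external_score, 0.975),
      external_p_lo = q(.data$external_p, 0.025),
      external_p_hi = q(.data$external_p, 0.975),
      discovery_fraction = mean(.data$discovery_fraction),
      discovery_score = mean(.data$discovery_score),
      external_score = mean(.data$external_score),
      external_p = mean(.data$external_p),
      .groups = "drop")
  structure(list(runs = runs, summary = summary, alpha = alpha,
                 budgets = budgets, strategies = strategies, seed = seed),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("<strategy_comparison> %d budgets x %d strategies, alpha=%g\n",
              length(x$budgets), length(x$strategies), x$alpha))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export a strategy comparison report
#'
#' Writes the per-cell summary (budget, split fractions, discovery
#' score, external score, p-value, conclusive count) as CSV or JSON.
#'
#' @param comparison a `strategy_comparison`.
#' @param path output file; `.json` extension selects JSON, else CSV.
#' @return the path, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  df <- as.data.frame(comparison$summary)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(alpha = comparison$alpha, seed = comparison$seed,
           strategies = comparison$strategies,
           budgets = comparison$budgets, summary = df),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
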