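test_that("fixed splits divide the budget as requested", {
  pool <- make_regression(140, 5, 0.6, seed = 10)
  out <- run_fixed(pool, 100, 0.5, seed = 1, final_perm = 199)
  expect_identical(out$n_discovery, 50L)
  expect_identical(out$n_validation, 50L)
  expect_gt(out$external_p, 0)
  expect_lte(out$external_p, 1)
  expect_error(run_fixed(pool, 200, 0.5, seed = 1),
               "budget exceeds available data")
})

test_that("strategies share the budget draw under a shared seed", {
  pool <- make_regression(140, 5, 0.6, seed = 10)
  a <- run_fixed(pool, 80, 0.5, seed = 7, final_perm = 99)
  b <- run_fixed(pool, 80, 0.9, seed = 7, final_perm = 99)
  expect_identical(a$rows, b$rows)
  cc <- replay_adaptive(pool, 80, seed = 7, lc_boot = 3, pow_boot = 10,
                        pow_perm = 49, final_perm = 99)
  expect_identical(a$rows, cc$rows)
})

test_that("adaptive replay with t_min + v_min = n_total equals the fixed split", {
  pool <- make_classification(150, 6, 2, seed = 20)
  prm <- rule_params(t_min = 80, v_min = 20)
  ad <- replay_adaptive(pool, 100, params = prm, seed = 31,
                        lc_boot = 3, pow_boot = 10, pow_perm = 49,
                        final_perm = 499)
  fx <- run_fixed(pool, 100, 0.8, seed = 31, final_perm = 499)
  expect_identical(ad$n_discovery, 80L)
  expect_identical(ad$n_discovery, fx$n_discovery)
  expect_identical(ad$external_score, fx$external_score)
  expect_identical(ad$external_p, fx$external_p)
})

test_that("replay terminates, keeps sets disjoint and honours the floors", {
  pool <- make_archetype("flat", 200, seed = 40)
  for (s in 1:3) {
    out <- replay_adaptive(pool, 60, seed = s, lc_boot = 4, pow_boot = 20,
                           pow_perm = 49, final_perm = 99)
    expect_identical(out$n_discovery + out$n_validation, out$n_total)
    expect_gte(out$n_validation, out$params$v_min)
    expect_gte(out$n_discovery, out$params$t_min)
    # acquisition order partitions the drawn rows without overlap
    expect_identical(length(unique(out$rows)), out$n_total)
    # n_act is strictly increasing along the trajectory
    n_acts <- vapply(out$trajectory, function(d) d$n_act, integer(1))
    expect_true(all(diff(n_acts) > 0))
  }
  expect_error(replay_adaptive(pool, 60, params = rule_params(t_min = 55),
                               seed = 1),
               "t_min \\+ v_min exceeds")
})

test_that("external validation applies the frozen model without refitting", {
  tr <- make_classification(80, 4, 3, seed = 8)
  va <- make_classification(40, 4, 3, seed = 9)
  m <- fit_tuned(tr, seed = 1)
  ev <- external_validate(m, va, "accuracy", n_perm = 499, seed = 2)
  expect_equal(ev$score, score(va$target, predict(m, va$features), "accuracy"))
  expect_gte(ev$p, 1 / 500)
  # a zero-signal model scores at chance and p is not extreme on average
  null_model <- m
  null_model$coefficients[] <- 0
  null_model$intercept <- 0
  ps <- sapply(1:10, function(s) {
    v <- make_classification(30, 4, 3, seed = 100 + s)
    external_validate(null_model, v, "accuracy", n_perm = 99, seed = s)$p
  })
  expect_gt(mean(ps), 0.2) # uniform p-values: mean near 0.5
  expect_error(external_validate(m, ds_slice(va, integer(0)), "accuracy"),
               "empty validation set")
})

test_that("larger fixed discovery fractions win on strong signal", {
  # high enough dimension that halving the training sample hurts
  pool <- make_regression(250, 20, 0.8, seed = 55)
  wins <- sapply(1:50, function(s) {
    big <- run_fixed(pool, 80, 0.9, spec = fast_spec("regression"),
                     seed = 700 + s, final_perm = 49)
    small <- run_fixed(pool, 80, 0.5, spec = fast_spec("regression"),
                       seed = 700 + s, final_perm = 49)
    big$external_score >= small$external_score
  })
  expect_gte(mean(wins), 0.7)
})

test_that("adaptive splitting protects validation power on weak signal", {
  pool <- make_archetype("flat", 250, seed = 60)
  spec <- fast_spec("classification")
  res <- sapply(1:25, function(s) {
    ad <- replay_adaptive(pool, 60, spec = spec, seed = 800 + s,
                          lc_boot = 4, pow_boot = 20, pow_perm = 49,
                          final_perm = 199)
    fx <- run_fixed(pool, 60, 0.9, spec = spec, seed = 800 + s,
                    final_perm = 199)
    c(adaptive = ad$external_p < 0.05, ninety = fx$external_p < 0.05)
  })
  expect_gte(mean(res["adaptive", ]), mean(res["ninety", ]))
})

test_that("compare_strategies aggregates exactly its component runs", {
  pool <- make_regression(120, 4, 0.6, seed = 70)
  cmp <- compare_strategies(pool, budgets = c(60, 80),
                            strategies = c("adaptive", "fixed:0.8"),
                            reps = 1, seed = 5, lc_boot = 3, pow_boot = 10,
                            pow_perm = 49, final_perm = 99)
  expect_identical(nrow(cmp$summary), 4L)
  expect_identical(nrow(cmp$runs), 4L)
  # reps = 1: summary means equal the single outcomes
  one <- cmp$runs[cmp$runs$strategy == "fixed:0.8" & cmp$runs$budget == 60, ]
  fx <- run_fixed(pool, 60, 0.8, seed = child_seed(5, 1000L, 1),
                  final_perm = 99)
  expect_equal(one$external_score, fx$external_score)
  expect_equal(one$external_p, fx$external_p)
  # export round-trip
  js <- tempfile(fileext = ".json")
  write_comparison(cmp, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(nrow(parsed$summary), 4L)
  expect_setequal(parsed$strategies, c("adaptive", "fixed:0.8"))
  unlink(js)
})
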