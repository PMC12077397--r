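# Independent oracles and small utilities shared across tests. These
# deliberately avoid the package's own code paths (and pracma, which the
# implementation uses for enumeration).

# all permutations of 1..n by simple recursion (test-side oracle)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# two-sided 99% normal-approximation band around p0 for a mean of n draws
binom_band <- function(p0, n) {
  hw <- 2.576 * sqrt(p0 * (1 - p0) / n)
  c(p0 - hw, p0 + hw)
}

expect_in_band <- function(x, band) {
  expect_gte(x, band[1])
  expect_lte(x, band[2])
}

# fast model spec used by simulation-heavy tests: 3 folds keep nested CV
# cheap without changing the contract under test
fast_spec <- function(task) model_spec(task, cv_folds = 3)

# fabricate a learning_curve object for extrapolation unit tests
fake_curve <- function(sizes, scores, scorer_id = "explained_variance") {
  structure(
    list(sizes = as.integer(sizes), scores = scores,
         ci_low = scores, ci_high = scores,
         boot_scores = matrix(scores, 1), n_boot = 1,
         scorer_id = scorer_id, n_act = max(sizes)),
    class = "learning_curve")
}

bcw_dataset <- function() {
  read_dataset(system.file("extdata", "bcw_subsample.csv",
                           package = "adasplit"),
               target_column = "diagnosis")
}
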