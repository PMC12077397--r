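test_that("separable toy problem is fit correctly and deterministically", {
  ds <- as_dataset(matrix(c(-1, -0.9, 0.9, 1), 4, 1), c(0, 0, 1, 1))
  m1 <- fit_tuned(ds, seed = 3)
  expect_identical(predict(m1, ds$features), c(0L, 0L, 1L, 1L))
  expect_equal(score(ds$target, predict(m1, ds$features), "accuracy"), 1.0)
  m2 <- fit_tuned(ds, seed = 3)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$chosen_regularization, m2$chosen_regularization)
})

test_that("degenerate and undersized inputs raise the documented errors", {
  expect_error(as_dataset(matrix(1:4, 2, 2), c(1, 1), task = "classification"),
               "degenerate target")
  ds <- make_regression(5, 3, 0.5, seed = 1)
  expect_error(make_folds(ds$target[1:3], "regression", 5, 1),
               "insufficient sample for cross-validation")
  expect_error(cv_predict(ds_slice(ds, 1:3)),
               "insufficient sample for cross-validation")
  m <- fit_tuned(ds, seed = 1)
  expect_error(predict(m, matrix(0, 2, 5)), "feature mismatch")
})

test_that("chosen regularization matches a closed-form brute-force oracle", {
  ds <- make_regression(60, 10, 0.5, rho = 0.7, seed = 7)
  spec <- model_spec("regression")
  m <- fit_tuned(ds, spec, seed = 42)

  # independent oracle: per grid value, closed-form ridge on the model's
  # own fold assignment (solve(X'X + lambda I) on fold-standardized data)
  folds <- m$folds
  grid <- spec$regularization_grid
  cv_scores <- sapply(grid, function(lam) {
    mean(sapply(seq_len(max(folds)), function(j) {
      tr <- folds != j
      Xtr <- ds$features[tr, , drop = FALSE]
      ctr <- colMeans(Xtr)
      str <- apply(Xtr, 2, sd)
      Xs_tr <- scale(Xtr, ctr, str)
      Xs_te <- scale(ds$features[!tr, , drop = FALSE], ctr, str)
      ytr <- ds$target[tr]
      beta <- solve(crossprod(Xs_tr) + lam * diag(ncol(Xs_tr)),
                    crossprod(Xs_tr, ytr - mean(ytr)))
      pred <- drop(Xs_te %*% beta) + mean(ytr)
      -mean(abs(ds$target[!tr] - pred))
    }))
  })
  best <- max(which(cv_scores >= max(cv_scores) - 1e-12))
  expect_equal(m$chosen_regularization, grid[best])
})

test_that("predictions are invariant to consistent feature rescaling", {
  ds <- make_regression(50, 6, 0.6, seed = 11)
  scl <- c(100, 0.01, 7, 1, 1000, 0.5)
  ds2 <- as_dataset(sweep(ds$features, 2, scl, "*"), ds$target, "regression")
  m1 <- fit_tuned(ds, seed = 4)
  m2 <- fit_tuned(ds2, seed = 4)
  Xnew <- matrix(rnorm(10 * 6), 10, 6)
  expect_equal(predict(m1, Xnew), predict(m2, sweep(Xnew, 2, scl, "*")),
               tolerance = 1e-6)
})

test_that("cv_predict partitions indices and no preprocessing leaks", {
  ds <- make_regression(40, 5, 0.5, seed = 2)
  ps <- cv_predict(ds, seed = 9)
  expect_identical(sort(unique(ps$folds)), seq_len(max(ps$folds)))
  expect_identical(tabulate(ps$folds, max(ps$folds)) |> sum(), 40L)
  expect_false(anyNA(ps$prediction))
  # per-fold preprocessing constants are learned inside each training
  # partition, so they must differ between folds
  centers <- vapply(ps$fold_details,
                    function(d) d$preprocessing$center[[1]], numeric(1))
  expect_gt(length(unique(centers)), 1)
})

test_that("nested CV score does not beat in-sample score in expectation", {
  diffs <- sapply(1:20, function(s) {
    ds <- make_regression(20, 4, 0.8, seed = 600 + s)
    m <- fit_tuned(ds, seed = s)
    in_s <- score(ds$target, predict(m, ds$features), "neg_mean_absolute_error")
    ps <- cv_predict(ds, seed = s)
    out_s <- score(ps$truth, ps$prediction, "neg_mean_absolute_error")
    in_s - out_s
  })
  expect_gt(mean(diffs), 0)
})

test_that("out-of-fold accuracy sits at chance for pure-noise labels", {
  accs <- sapply(1:50, function(s) {
    ds <- make_classification(100, p = 10, target_signal = 0, seed = 1000 + s)
    ps <- cv_predict(ds, seed = s)
    score(ps$truth, ps$prediction, "accuracy")
  })
  expect_in_band(mean(accs), binom_band(0.5, 50 * 100))
})

test_that("scorers match their definitions and bounds", {
  expect_equal(score(c(0, 1, 1), c(0, 1, 1), "accuracy"), 1.0)
  expect_equal(score(c(0, 2), c(1, 3), "neg_mean_absolute_error"), -1.0)
  expect_equal(score(c(1, 2, 4), c(1, 2, 4), "explained_variance"), 1.0)
  expect_error(score(numeric(0), numeric(0), "accuracy"), "empty score input")
  expect_error(score(c(1, 1, 1), c(1, 2, 3), "explained_variance"),
               "zero-variance target")
  for (s in 1:10) {
    set.seed(s)
    t <- rnorm(20); p <- rnorm(20)
    expect_lte(score(t, p, "neg_mean_absolute_error"), 0)
    expect_lte(score(t, p, "explained_variance"), 1)
    a <- score(rbinom(20, 1, 0.5), rbinom(20, 1, 0.5), "accuracy")
    expect_gte(a, 0); expect_lte(a, 1)
  }
  expect_equal(get_scorer("accuracy")$chance(c(0, 0, 0, 1)), 0.75)
})
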