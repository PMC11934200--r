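toy_X <- function(n, d = 20, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * d, 1, 0.3), n, d,
              dimnames = list(NULL, paste0("bit", seq_len(d) - 1)))
  X
}

test_that("upsampling balances classes by resampling the minority", {
  X <- toy_X(100)
  y <- rep(c(0L, 1L), c(90, 10))
  up <- upsample_minority(X, y, seed = 3)
  expect_equal(sum(up$y == 0), 90)
  expect_equal(sum(up$y == 1), 90)
  expect_true(all(up$idx[up$y == 1] %in% 91:100))
  # balanced input keeps its size; seeded runs are identical
  yb <- rep(c(0L, 1L), each = 50)
  expect_length(upsample_minority(X, yb, seed = 1)$y, 100)
  expect_identical(upsample_minority(X, y, seed = 5),
                   upsample_minority(X, y, seed = 5))
  expect_error(upsample_minority(X, rep(1L, 100)), "both classes")
})

test_that("the 80/20 split is disjoint and stratified", {
  y <- rep(c(0L, 1L), c(80, 20))
  sp <- train_validation_split(y, 0.2, seed = 2)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_equal(sort(c(sp$train, sp$validation)), seq_along(y))
  expect_equal(length(sp$validation), 20)
  expect_equal(sum(y[sp$validation]), 4)
})

test_that("stratified folds always contain both classes or fail loudly", {
  y <- rep(c(0L, 1L), c(30, 12))
  fold <- stratified_folds(y, k = 3, seed = 1)
  for (f in 1:3) expect_setequal(unique(y[fold == f]), c(0, 1))
  expect_error(stratified_folds(rep(c(0L, 1L), c(40, 2)), k = 5),
               "does not contain both classes")
})

test_that("the forest is seeded, bounded and probabilistic", {
  X <- toy_X(80)
  y <- as.integer(rowSums(X[, 1:3]) >= 2)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  m1 <- fit_forest(X, y, 100, 5, seed = 7)
  m2 <- fit_forest(X, y, 100, 5, seed = 7)
  p1 <- predict(m1, X); p2 <- predict(m2, X)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(fit_forest(X, rep(1L, 80), 100, 5), "both classes")
})

test_that("a pure deep forest memorizes separable training data", {
  X <- toy_X(60, seed = 11)
  y <- as.integer(X[, 1] == 1)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  m <- fit_forest(X, y, 200, 19, seed = 1)
  p <- predict(m, X)
  expect_true(all((p >= 0.5) == (y == 1)))
  expect_gte(m$train_auc, 0.99)
})

test_that("randomized search respects bounds and logs all draws", {
  fx <- fx_zero_noise()
  sub <- c(which(fx$y == 1)[1:60], which(fx$y == 0)[1:60])
  sp <- search_space(n_draws = 3, seed = 5)
  res <- search_hyperparameters(fx$X[sub, ], fx$y[sub], sp, k = 3)
  expect_equal(nrow(res$draws), 3)
  expect_true(all(res$draws$n_estimators >= 50 & res$draws$n_estimators <= 500))
  expect_true(all(res$draws$max_depth >= 1 & res$draws$max_depth <= 20))
  expect_equal(res$best$mean_auc, max(res$draws$mean_auc))
  one <- search_hyperparameters(fx$X[sub, ], fx$y[sub],
                                search_space(n_draws = 1, seed = 5), k = 3)
  expect_equal(one$best$n_estimators, one$draws$n_estimators[1])
})

test_that("zero-noise planted data is learnable: CV ROC-AUC >= 0.95", {
  fx <- fx_zero_noise()
  res <- cv_auc(fx$X, fx$y, n_estimators = 300, max_depth = 19, k = 5,
                seed = 2)
  expect_gte(res$mean_auc, 0.95)
})

test_that("CV ROC-AUC is stable across k in {3, 5, 10} on clean data", {
  fx <- fx_zero_noise()
  means <- vapply(c(3, 5, 10), function(k) {
    cv_auc(fx$X, fx$y, n_estimators = 200, max_depth = 19, k = k,
           seed = 4)$mean_auc
  }, numeric(1))
  expect_lt(max(means) - min(means), 0.05)
})
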