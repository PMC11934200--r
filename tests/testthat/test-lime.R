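test_that("the neighborhood starts at the instance with proximity one", {
  d <- 50
  set.seed(1)
  x <- rbinom(d, 1, 0.5); names(x) <- paste0("bit", 0:(d - 1))
  freqs <- runif(d, 0.1, 0.9)
  nb <- sample_neighborhood(x, freqs, explainer_config(num_samples = 200,
                                                       seed = 2))
  expect_identical(nb$perturbed[1, ], x)
  expect_true(all(nb$interpretable[1, ] == 1))
  expect_equal(nb$proximity[1], 1)
  expect_error(sample_neighborhood(x, rep(0, d), explainer_config()),
               "all-zero")
})

test_that("proximity decays monotonically with interpretable mismatches", {
  d <- 50
  x <- rep(1L, d); names(x) <- paste0("bit", 0:(d - 1))
  nb <- sample_neighborhood(x, rep(0.5, d),
                            explainer_config(num_samples = 500, seed = 3))
  mism <- d - rowSums(nb$interpretable)
  ord <- order(mism)
  expect_true(all(diff(nb$proximity[ord]) <= 1e-12))
})

test_that("perturbed bits follow the training frequencies", {
  d <- 1024
  set.seed(5)
  freqs <- runif(d)
  x <- rbinom(d, 1, freqs); names(x) <- paste0("bit", 0:(d - 1))
  nb <- sample_neighborhood(x, freqs, explainer_config(num_samples = 5000,
                                                       seed = 6))
  means <- colMeans(nb$perturbed[-1, ])
  se <- sqrt(freqs * (1 - freqs) / (nrow(nb$perturbed) - 1))
  inner <- se > 0
  expect_true(all(abs(means[inner] - freqs[inner]) <= 3.5 * se[inner]))
})

test_that("a constant model yields no weights and is flagged", {
  d <- 64
  x <- rep(1L, d); names(x) <- paste0("bit", 0:(d - 1))
  e <- explain_instance(function(X) rep(0.7, nrow(X)), x, rep(0.5, d),
                        explainer_config(num_samples = 300, seed = 1))
  expect_true(e$constant_model)
  expect_equal(nrow(e$weights), 0)
  expect_equal(e$model_probability, 0.7)
})

test_that("an indicator model puts its bit on top with positive weight", {
  d <- 128
  j <- 17  # 0-based bit index
  x <- rep(0L, d); x[j + 1] <- 1L; names(x) <- paste0("bit", 0:(d - 1))
  model <- function(X) X[, j + 1]
  e <- explain_instance(model, x, rep(0.5, d),
                        explainer_config(num_features = 10,
                                         num_samples = 2000, seed = 4))
  expect_equal(e$weights$bit[1], j)
  expect_gt(e$weights$weight[1], 0.5)
  expect_true(all(abs(e$weights$weight[-1]) < 0.1))
  # ablation oracle: flipping bit j moves the model by 1, others by 0
  flip_effect <- vapply(seq_len(d), function(b) {
    x2 <- x; x2[b] <- 1L - x2[b]
    model(rbind(x2)) - model(rbind(x))
  }, numeric(1))
  expect_equal(which.max(abs(flip_effect)), j + 1)
})

test_that("weights recover known logistic coefficients in rank order", {
  rhos <- vapply(1:5, logistic_recovery_rho, numeric(1))
  expect_gte(median(rhos), 0.9)
})

test_that("explanations are deterministic given the seed", {
  d <- 256
  set.seed(2)
  x <- rbinom(d, 1, 0.4); names(x) <- paste0("bit", 0:(d - 1))
  model <- function(X) plogis(rowSums(X[, 1:5, drop = FALSE]) - 2)
  cfg <- explainer_config(num_samples = 500, seed = 11)
  e1 <- explain_instance(model, x, rep(0.4, d), cfg)
  e2 <- explain_instance(model, x, rep(0.4, d), cfg)
  expect_identical(e1$weights, e2$weights)
  expect_identical(e1$fit_quality, e2$fit_quality)
})

test_that("weights are bounded and capped at the feature budget", {
  d <- 256
  set.seed(3)
  x <- rbinom(d, 1, 0.5); names(x) <- paste0("bit", 0:(d - 1))
  model <- function(X) plogis(5 * X[, 1] - 2)
  e <- explain_instance(model, x, rep(0.5, d),
                        explainer_config(num_features = 20,
                                         num_samples = 500, seed = 5))
  expect_lte(nrow(e$weights), 20)
  expect_true(all(e$weights$weight >= -1 & e$weights$weight <= 1))
})

test_that("the surrogate fits a nearly linear model faithfully", {
  d <- 128
  set.seed(6)
  beta <- c(runif(6, 0.5, 1.5), rep(0, d - 6))
  x <- rbinom(d, 1, 0.5); names(x) <- paste0("bit", 0:(d - 1))
  model <- function(X) plogis(drop(X %*% beta) - 2)
  e <- explain_instance(model, x, rep(0.5, d),
                        explainer_config(num_samples = 2000, seed = 7))
  expect_gte(e$fit_quality, 0.8)
})
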