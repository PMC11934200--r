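#' Hyperparameter search space for the random forest
#'
#' @param n_estimators integer bounds for the number of trees (default
#'   c(50, 500)).
#' @param max_depth integer bounds for the maximum tree depth (default
#'   c(1, 20)).
#' @param n_draws number of random configurations to score (default 20).
#' @param seed integer seed for the draws.
#' @return object of class `search_space`.
#' @export
search_space <- function(n_estimators = c(50L, 500L), max_depth = c(1L, 20L),
                         n_draws = 20L, seed = 1L) {
  stopifnot(length(n_estimators) == 2, length(max_depth) == 2,
            n_estimators[1] <= n_estimators[2],
            max_depth[1] >= 1, max_depth[1] <= max_depth[2], n_draws >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "search_space")
}

#' Upsample the minority class
#'
#' Resamples minority-class rows with replacement until both classes have
#' equal counts, then shuffles the row order. Doing this before a
#' train/validation split leaks duplicated rows across the split; see
#' [run_pipeline()]'s `upsample_timing` argument.
#'
#' @param X feature matrix (rows = molecules).
#' @param y binary labels aligned to rows.
#' @param seed integer seed.
#' @return list with the balanced `X`, `y`, and `idx` (the original row
#'   index of every output row).
#' @export
upsample_minority <- function(X, y, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("upsample_minority needs both classes present")
  minority <- as.integer(names(which.min(tab)))
  n_extra <- abs(diff(as.integer(tab)))
  idx <- seq_along(y)
  withr::with_seed(seed, {
    if (n_extra > 0) {
      extra <- sample(which(y == minority), n_extra, replace = TRUE)
      idx <- c(idx, extra)
    }
    idx <- sample(idx)
  })
  list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx)
}

#' Stratified train/validation split
#'
#' @param y binary labels.
#' @param val_frac validation fraction (default 0.2).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `validation`.
#' @export
train_validation_split <- function(y, val_frac = 0.2, seed = 1L) {
  stopifnot(val_frac > 0, val_frac < 1)
  withr::with_seed(seed, {
    val <- unlist(lapply(unique(y), function(cl) {
      i <- which(y == cl)
      sample(i, max(1L, round(length(i) * val_frac)))
    }))
  })
  val <- sort(val)
  list(train = setdiff(seq_along(y), val), validation = val)
}

#' Stratified k-fold assignment
#'
#' @param y binary labels.
#' @param k fold count (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k; errors if any fold would
#'   miss a class.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      i <- sample(which(y == cl))
      fold[i] <- rep_len(seq_len(k), length(i))
    }
  })
  for (f in seq_len(k)) {
    if (length(unique(y[fold == f])) < 2) {
      stop("fold ", f, " does not contain both classes; ",
           "use fewer folds or more data")
    }
  }
  fold
}

#' Fit the random-forest probability classifier
#'
#' @param X binary feature matrix with column names.
#' @param y binary labels.
#' @param n_estimators number of trees.
#' @param max_depth maximum tree depth.
#' @param seed integer seed (forest growth is deterministic given it).
#' @return object of class `rf_model`.
#' @export
fit_forest <- function(X, y, n_estimators = 300L, max_depth = 19L, seed = 1L) {
  if (length(unique(y)) < 2) stop("fit_forest needs both classes present")
  yf <- factor(y, levels = c(0, 1))
  forest <- ranger::ranger(
    x = X, y = yf, num.trees = as.integer(n_estimators),
    max.depth = as.integer(max_depth), probability = TRUE,
    seed = as.integer(seed), num.threads = 1
  )
  prob_train <- predict(forest, data = X, num.threads = 1)$predictions[, "1"]
  structure(list(
    forest = forest,
    params = list(n_estimators = as.integer(n_estimators),
                  max_depth = as.integer(max_depth)),
    seed = as.integer(seed),
    feature_names = colnames(X),
    train_auc = roc_auc(prob_train, y)
  ), class = "rf_model")
}

#' Class-1 probability predictions
#'
#' @param object an `rf_model`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.rf_model <- function(object, newdata, ...) {
  stopifnot(identical(colnames(newdata), object$feature_names))
  predict(object$forest, data = newdata, num.threads = 1)$predictions[, "1"]
}

#' @export
print.rf_model <- function(x, ...) {
  cat("<rf_model> ", x$params$n_estimators, " trees, max depth ",
      x$params$max_depth, ", training ROC-AUC ",
      sprintf("%.3f", x$train_auc), "\n", sep = "")
  invisible(x)
}

# Internal: predict through either an rf_model or a plain function, so the
# explainer can be exercised against analytically known models in tests.
.predict_prob <- function(model, X) {
  if (inherits(model, "rf_model")) predict(model, X) else model(X)
}

#' Mean cross-validated ROC-AUC of one configuration
#'
#' @param X,y data.
#' @param n_estimators,max_depth forest configuration.
#' @param k fold count.
#' @param seed integer seed (folds and forests).
#' @return list with `mean_auc` and per-fold `fold_aucs`.
#' @export
cv_auc <- function(X, y, n_estimators, max_depth, k = 5L, seed = 1L) {
  fold <- stratified_folds(y, k = k, seed = seed)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    m <- fit_forest(X[tr, , drop = FALSE], y[tr], n_estimators, max_depth,
                    seed = seed + f)
    roc_auc(predict(m, X[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  list(mean_auc = mean(aucs), fold_aucs = aucs)
}

#' Randomized hyperparameter search
#'
#' Draws `n_draws` random (n_estimators, max_depth) configurations from the
#' search space, scores each by mean stratified k-fold ROC-AUC, and returns
#' the argmax along with the full log of draws.
#'
#' @param X,y data (typically after upsampling).
#' @param space a [search_space()].
#' @param k fold count (default 5).
#' @return object of class `hyper_search`: `best` (list with n_estimators,
#'   max_depth, mean_auc, fold_aucs) and `draws` (data.frame log).
#' @export
search_hyperparameters <- function(X, y, space = search_space(), k = 5L) {
  stopifnot(inherits(space, "search_space"), k >= 2)
  withr::with_seed(space$seed, {
    ne <- sample(space$n_estimators[1]:space$n_estimators[2],
                 space$n_draws, replace = TRUE)
    md <- sample(space$max_depth[1]:space$max_depth[2],
                 space$n_draws, replace = TRUE)
  })
  res <- lapply(seq_len(space$n_draws), function(d) {
    cv_auc(X, y, ne[d], md[d], k = k, seed = space$seed + d)
  })
  draws <- data.frame(
    n_estimators = ne, max_depth = md,
    mean_auc = vapply(res, `[[`, numeric(1), "mean_auc")
  )
  best_i <- which.max(draws$mean_auc)
  structure(list(
    best = list(n_estimators = ne[best_i], max_depth = md[best_i],
                mean_auc = draws$mean_auc[best_i],
                fold_aucs = res[[best_i]]$fold_aucs),
    draws = draws, k = k
  ), class = "hyper_search")
}

#' @export
print.hyper_search <- function(x, ...) {
  cat("<hyper_search> ", nrow(x$draws), " draws, ", x$k, "-fold CV; best: ",
      x$best$n_estimators, " trees, depth ", x$best$max_depth,
      ", mean ROC-AUC ", sprintf("%.3f", x$best$mean_auc), "\n", sep = "")
  invisible(x)
}
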