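#' Configuration of the local surrogate explainer
#'
#' @param num_features how many bits the sparse surrogate may use
#'   (default 100).
#' @param num_samples size of the perturbation neighborhood (default 5000,
#'   at which the neighborhood moments are stable; minimum 100).
#' @param kernel_width proximity-kernel width; default 0.75 * sqrt(d) with
#'   d the fingerprint length, the conventional choice for binary features.
#' @param num_explanations explanations produced per molecule (default 1:
#'   a single explanation of the predicted class).
#' @param seed integer seed for the perturbation sampling.
#' @return object of class `explainer_config`.
#' @export
explainer_config <- function(num_features = 100L, num_samples = 5000L,
                             kernel_width = NULL, num_explanations = 1L,
                             seed = 1L) {
  stopifnot(num_features >= 1, num_samples >= 100,
            is.null(kernel_width) || kernel_width > 0)
  structure(list(
    num_features = as.integer(num_features),
    num_samples = as.integer(num_samples),
    kernel_width = kernel_width,
    num_explanations = as.integer(num_explanations),
    seed = as.integer(seed)
  ), class = "explainer_config")
}

.kernel_width <- function(cfg, d) {
  if (!is.null(cfg$kernel_width)) cfg$kernel_width else 0.75 * sqrt(d)
}

#' Sample a perturbation neighborhood around an instance
#'
#' Each perturbed bit is drawn independently from its Bernoulli frequency
#' in the training set. The interpretable representation marks agreement
#' with the instance (1 = bit equals the instance's value), and proximity
#' weights are exp(-D^2 / sigma^2) with D the Euclidean distance on the
#' interpretable representation. The first row is the instance itself, at
#' proximity 1.
#'
#' @param x binary fingerprint vector of the instance.
#' @param train_frequencies per-bit activation frequencies of the training
#'   set (e.g. `colMeans(X_train)`).
#' @param cfg an [explainer_config()].
#' @return list with `perturbed` (num_samples x d 0/1 matrix),
#'   `interpretable` (same shape), and `proximity` (num_samples weights).
#' @export
sample_neighborhood <- function(x, train_frequencies, cfg = explainer_config()) {
  d <- length(x)
  stopifnot(length(train_frequencies) == d)
  if (all(train_frequencies == 0)) {
    stop("all-zero training bit frequencies: nothing to perturb")
  }
  n <- cfg$num_samples
  withr::with_seed(cfg$seed, {
    perturbed <- matrix(
      as.integer(runif(n * d) < rep(train_frequencies, each = n)), n, d)
  })
  perturbed[1, ] <- as.integer(x)
  interpretable <- 1L * (perturbed == rep(as.integer(x), each = n))
  dsq <- d - rowSums(interpretable)
  sigma <- .kernel_width(cfg, d)
  proximity <- exp(-dsq / sigma^2)
  colnames(perturbed) <- colnames(interpretable) <- names(x)
  list(perturbed = perturbed, interpretable = interpretable,
       proximity = proximity)
}

# Weighted ridge with unpenalized intercept; returns coefficients (without
# intercept), fitted values and weighted R^2.
.weighted_ridge <- function(Z, y, w, lambda = 1) {
  n <- nrow(Z); p <- ncol(Z)
  Za <- cbind(1, Z)
  sw <- sqrt(w)
  A <- crossprod(Za * sw)
  pen <- diag(c(0, rep(lambda, p)))
  b <- crossprod(Za, w * y)
  beta <- solve(A + pen, b)
  fitted <- drop(Za %*% beta)
  ybar <- sum(w * y) / sum(w)
  ss_res <- sum(w * (y - fitted)^2)
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(coef = drop(beta)[-1], intercept = drop(beta)[1], r2 = r2)
}

#' Explain one prediction with a local linear surrogate
#'
#' Scores the model's class-1 probability on a perturbation neighborhood of
#' the instance, pre-fits a proximity-weighted ridge regression on all bits,
#' keeps the `num_features` bits with the largest-magnitude coefficients,
#' refits the weighted ridge on those, and returns the refit coefficients
#' (clipped to \[-1, 1\]) as per-bit contribution weights. A weight near +1
#' marks a bit pushing the prediction towards the active (disruptor) class,
#' a negative weight the opposite.
#'
#' @param model an `rf_model`, or any function mapping a 0/1 matrix to
#'   class-1 probabilities (useful for testing against known models).
#' @param x binary fingerprint vector of the instance (named by bit).
#' @param train_frequencies per-bit training-set frequencies.
#' @param cfg an [explainer_config()].
#' @param mol_id identifier carried into the result.
#' @return object of class `local_explanation`: `mol_id`,
#'   `model_probability`, `weights` (data.frame `bit`, `weight`, sorted by
#'   |weight| descending; `bit` is 0-based), `fit_quality` (weighted R^2),
#'   `constant_model` flag, and the config echo.
#' @export
explain_instance <- function(model, x, train_frequencies,
                             cfg = explainer_config(), mol_id = NULL) {
  nb <- sample_neighborhood(x, train_frequencies, cfg)
  prob <- .predict_prob(model, nb$perturbed)
  stopifnot(length(prob) == nrow(nb$perturbed))
  d <- length(x)
  k <- min(cfg$num_features, d)
  if (sd(prob) == 0) {
    expl <- list(
      mol_id = mol_id, model_probability = prob[1],
      weights = data.frame(bit = integer(0), weight = numeric(0)),
      fit_quality = NA_real_, constant_model = TRUE, config = cfg
    )
    class(expl) <- "local_explanation"
    return(expl)
  }
  pre <- .weighted_ridge(nb$interpretable, prob, nb$proximity)
  sel <- order(abs(pre$coef), decreasing = TRUE)[seq_len(k)]
  refit <- .weighted_ridge(nb$interpretable[, sel, drop = FALSE], prob,
                           nb$proximity)
  w <- pmax(-1, pmin(1, refit$coef))
  ord <- order(abs(w), decreasing = TRUE)
  expl <- list(
    mol_id = mol_id,
    model_probability = prob[1],
    weights = data.frame(bit = sel[ord] - 1L, weight = w[ord]),
    fit_quality = refit$r2,
    constant_model = FALSE,
    config = cfg
  )
  class(expl) <- "local_explanation"
  expl
}

#' @export
print.local_explanation <- function(x, ...) {
  cat("<local_explanation> ", if (!is.null(x$mol_id)) x$mol_id else "?",
      ": p(active) = ", sprintf("%.3f", x$model_probability), sep = "")
  if (x$constant_model) {
    cat(" [constant model output; no weights]\n")
  } else {
    cat(", surrogate R^2 = ", sprintf("%.3f", x$fit_quality),
        "; top bits:\n", sep = "")
    print(head(x$weights, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Explain a set of molecules
#'
#' Runs [explain_instance()] on each row of a feature matrix, deriving one
#' sub-seed per molecule from the config seed so the whole set is
#' reproducible.
#'
#' @param model an `rf_model` or probability function.
#' @param X feature matrix (rows = molecules to explain).
#' @param train_frequencies per-bit training-set frequencies.
#' @param cfg an [explainer_config()].
#' @return named list of `local_explanation` objects.
#' @export
explain_set <- function(model, X, train_frequencies,
                        cfg = explainer_config()) {
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  out <- lapply(seq_len(nrow(X)), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- (cfg$seed + 7919L * i) %% 2147483647L
    explain_instance(model, X[i, ], train_frequencies, cfg_i,
                     mol_id = ids[i])
  })
  names(out) <- ids
  out
}

#' Serialize explanations to JSON
#'
#' @param explanations list of `local_explanation` objects.
#' @param path output file.
#' @return (invisibly) `path`.
#' @export
write_explanations <- function(explanations, path) {
  payload <- lapply(explanations, function(e) {
    list(mol_id = e$mol_id, model_probability = e$model_probability,
         weights = e$weights, fit_quality = e$fit_quality,
         constant_model = e$constant_model,
         config = e$config[c("num_features", "num_samples",
                             "num_explanations", "seed")])
  })
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}
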