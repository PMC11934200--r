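# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

thiophosphate_spec <- function(n_active = 250, n_inactive = 250, seed = 101) {
  pats <- default_alert_patterns()
  synthetic_spec(
    n_active = n_active, n_inactive = n_inactive,
    alert_patterns = pats[pats$name == "thiophosphate", , drop = FALSE],
    label_noise = 0, seed = seed
  )
}

# 500-molecule zero-noise set with a single planted thiophosphate, plus its
# fingerprint matrix: the learnability fixture several suites share.
fx_zero_noise <- function() {
  fixture("zero_noise", function() {
    ds <- generate_synthetic(thiophosphate_spec())
    fm <- feature_matrix(ds$records$smiles, ids = ds$records$mol_id)
    y <- ds$records[["NR-AR"]][match(rownames(fm$X), ds$records$mol_id)]
    list(ds = ds, X = fm$X, y = y)
  })
}

# Noisy, imbalanced set for the leakage comparison.
fx_noisy <- function() {
  fixture("noisy", function() {
    ds <- generate_synthetic(synthetic_spec(
      n_active = 100, n_inactive = 300, label_noise = 0.15, seed = 3))
    fm <- feature_matrix(ds$records$smiles, ids = ds$records$mol_id)
    y <- ds$records[["NR-AR"]][match(rownames(fm$X), ds$records$mol_id)]
    list(ds = ds, X = fm$X, y = y)
  })
}

# Structurally unique base records with known injected duplicates,
# conflicts and salts, for exact curation-audit checks.
fx_injected <- function() {
  fixture("injected", function() {
    ds <- generate_synthetic(synthetic_spec(
      n_active = 60, n_inactive = 60, label_noise = 0, seed = 5))
    base <- curate_task(ds$records, "NR-AR")$records
    ds$records <- base
    inj <- inject_duplicates(ds, n_dup = 3, n_conflict = 2, n_salt = 2,
                             seed = 9)
    list(base = base, injected = inj)
  })
}

# Independent brute-force metric implementations (element-wise tallies and
# exhaustive pair counts), used as oracles against the package's formulas.
brute_confusion <- function(y_true, y_pred) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

brute_auc <- function(scores, y_true) {
  pos <- scores[y_true == 1]; neg <- scores[y_true == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

brute_kappa <- function(y_true, y_pred) {
  n <- length(y_true)
  po <- mean(y_true == y_pred)
  pe <- mean(y_true == 1) * mean(y_pred == 1) +
    mean(y_true == 0) * mean(y_pred == 0)
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

brute_mcc <- function(y_true, y_pred) {
  cc <- brute_confusion(y_true, y_pred)
  num <- cc["TP"] * cc["TN"] - cc["FP"] * cc["FN"]
  den <- sqrt(cc["TP"] + cc["FP"]) * sqrt(cc["TP"] + cc["FN"]) *
    sqrt(cc["TN"] + cc["FP"]) * sqrt(cc["TN"] + cc["FN"])
  if (den == 0) 0 else unname(num / den)
}

# Spearman correlation between sign-aligned surrogate weights and the true
# coefficients of a known logistic model (the instance-relative weight of a
# bit explains agreement with the instance, so bits that are off in the
# instance flip sign).
logistic_recovery_rho <- function(seed, num_samples = 1000) {
  d <- 1024
  set.seed(42)
  active_bits <- sample(0:(d - 1), 10)
  beta <- runif(10, 0.5, 2) * sample(c(-1, 1), 10, replace = TRUE)
  model <- function(X) {
    drop(stats::plogis(X[, active_bits + 1, drop = FALSE] %*% beta - mean(beta)))
  }
  set.seed(seed)
  x <- stats::rbinom(d, 1, 0.5)
  names(x) <- paste0("bit", 0:(d - 1))
  e <- explain_instance(model, x, rep(0.5, d),
                        explainer_config(num_samples = num_samples,
                                         seed = seed))
  w <- stats::setNames(rep(0, 10), active_bits)
  m <- match(active_bits, e$weights$bit)
  w[!is.na(m)] <- e$weights$weight[m[!is.na(m)]]
  sgn <- ifelse(x[active_bits + 1] == 1, 1, -1)
  stats::cor(w * sgn, beta, method = "spearman")
}

# Before-split vs after-split oversampling AUC on a fixed noisy dataset.
leakage_auc_pair <- function(X, y, seed) {
  up <- upsample_minority(X, y, seed = seed)
  sp <- train_validation_split(up$y, 0.2, seed = seed + 1)
  mb <- fit_forest(up$X[sp$train, ], up$y[sp$train], 300, 19, seed = seed + 2)
  before <- roc_auc(predict(mb, up$X[sp$validation, ]), up$y[sp$validation])
  sp2 <- train_validation_split(y, 0.2, seed = seed + 1)
  up2 <- upsample_minority(X[sp2$train, ], y[sp2$train], seed = seed)
  ma <- fit_forest(up2$X, up2$y, 300, 19, seed = seed + 2)
  after <- roc_auc(predict(ma, X[sp2$validation, ]), y[sp2$validation])
  c(before = before, after = after)
}
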