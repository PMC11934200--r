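#' Pipeline configuration
#'
#' Bundles every stage's settings under one seed. The input is either a
#' molecule table (data.frame or CSV path) or a [synthetic_spec()] to be
#' simulated.
#'
#' @param input data.frame, CSV path, or `synthetic_spec`.
#' @param task assay column to model.
#' @param seed master seed; every stochastic stage derives from it.
#' @param space a [search_space()], or NULL to skip the randomized search
#'   and use `params` directly.
#' @param params list(n_estimators, max_depth) used when `space` is NULL
#'   (default 300 trees, depth 19).
#' @param k fold count for cross-validation (default 5).
#' @param val_frac validation fraction of the 80/20 split (default 0.2).
#' @param upsample_timing `"before"` (oversample the minority class before
#'   splitting — the protocol under study, optimistic because duplicated
#'   rows straddle the split) or `"after"` (leakage-safe: split first,
#'   oversample the training portion only).
#' @param explainer an [explainer_config()].
#' @param confidence probability threshold for confident actives
#'   (default 0.8).
#' @param weight_floor minimum attribution weight kept in the alert table
#'   (default 0.1).
#' @param curate curate the input table before modeling (default TRUE).
#' @param output_dir if non-NULL, stage outputs are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, task, seed = 1L, space = NULL,
                            params = list(n_estimators = 300L,
                                          max_depth = 19L),
                            k = 5L, val_frac = 0.2,
                            upsample_timing = c("before", "after"),
                            explainer = explainer_config(),
                            confidence = 0.8, weight_floor = 0.1,
                            curate = TRUE, output_dir = NULL) {
  upsample_timing <- match.arg(upsample_timing)
  if (!is.null(space)) stopifnot(inherits(space, "search_space"))
  stopifnot(inherits(explainer, "explainer_config"),
            confidence >= 0, confidence <= 1)
  structure(list(
    input = input, task = task, seed = as.integer(seed), space = space,
    params = params, k = as.integer(k), val_frac = val_frac,
    upsample_timing = upsample_timing, explainer = explainer,
    confidence = confidence, weight_floor = weight_floor,
    curate = curate, output_dir = output_dir
  ), class = "pipeline_config")
}

.load_input <- function(config) {
  inp <- config$input
  if (inherits(inp, "synthetic_spec")) {
    ds <- generate_synthetic(inp)
    return(ds$records)
  }
  if (is.character(inp)) return(read_molecule_table(inp))
  stopifnot(is.data.frame(inp))
  inp
}

#' Run the full alert-mining pipeline
#'
#' Executes curate -> featurize -> balance/split -> (search) -> train ->
#' evaluate -> explain -> mine-alerts for one task, under one seed, and
#' returns everything a report needs. With an `output_dir` set in the
#' config, the audit (JSON), validation metrics (CSV), explanations (JSON),
#' alert table (CSV) and a run manifest (JSON) are also written.
#'
#' @param config a [pipeline_config()].
#' @return object of class `toxalert_run` with elements `manifest`,
#'   `audit`, `model`, `search`, `metrics`, `explanations`, `attributions`,
#'   `verdicts`, and `alert_table`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  records <- .load_input(config)
  if (!config$task %in% names(records)) {
    stop("unknown task '", config$task, "'; table has: ",
         paste(setdiff(names(records), c("mol_id", "smiles")), collapse = ", "))
  }
  tick("load")

  audit <- NULL
  if (isTRUE(config$curate)) {
    cur <- curate_task(records, config$task)
    records <- cur$records
    audit <- cur$audit
  }
  tick("curate")

  fm <- feature_matrix(records$smiles, ids = records$mol_id,
                       keep_fingerprints = TRUE)
  X <- fm$X
  y <- records[[config$task]][match(rownames(X), records$mol_id)]
  tick("featurize")

  if (config$upsample_timing == "before") {
    up <- upsample_minority(X, y, seed = config$seed)
    sp <- train_validation_split(up$y, config$val_frac,
                                 seed = config$seed + 1L)
    X_tr <- up$X[sp$train, , drop = FALSE]; y_tr <- up$y[sp$train]
    X_va <- up$X[sp$validation, , drop = FALSE]; y_va <- up$y[sp$validation]
  } else {
    sp <- train_validation_split(y, config$val_frac, seed = config$seed + 1L)
    up <- upsample_minority(X[sp$train, , drop = FALSE], y[sp$train],
                            seed = config$seed)
    X_tr <- up$X; y_tr <- up$y
    X_va <- X[sp$validation, , drop = FALSE]; y_va <- y[sp$validation]
  }
  tick("split")

  search <- NULL
  if (!is.null(config$space)) {
    search <- search_hyperparameters(X_tr, y_tr, config$space, k = config$k)
    params <- search$best
  } else {
    params <- config$params
  }
  model <- fit_forest(X_tr, y_tr, params$n_estimators, params$max_depth,
                      seed = config$seed + 2L)
  tick("train")

  prob_va <- predict(model, X_va)
  metrics <- metrics_report(y_va, prob_va, task = config$task)
  tick("evaluate")

  freqs <- colMeans(X_tr)
  conf_idx <- which(y_va == 1 & prob_va >= max(config$confidence, 0.5))
  cfg_ex <- config$explainer
  cfg_ex$seed <- config$seed + 3L
  explanations <- explain_set(model, X_va[conf_idx, , drop = FALSE],
                              freqs, cfg_ex)
  tick("explain")

  att_list <- lapply(names(explanations), function(id) {
    attribute_fragments(explanations[[id]], fm$fingerprints[[id]])
  })
  attributions <- if (length(att_list)) do.call(rbind, att_list) else NULL
  verdicts <- lapply(att_list, molecule_verdict)
  alert_tab <- if (is.null(attributions) || nrow(attributions) == 0) {
    # no confident disruptor found: an empty alert table is a valid outcome
    structure(data.frame(fragment_smiles = character(0),
                         occurrences = integer(0),
                         total_weight = numeric(0)),
              class = c("alert_table", "data.frame"))
  } else {
    aggregate_alerts(attributions, config$weight_floor)
  }
  tick("mine_alerts")

  manifest <- list(
    task = config$task, seed = config$seed,
    upsample_timing = config$upsample_timing,
    n_input = nrow(records), n_train = nrow(X_tr),
    n_validation = nrow(X_va),
    n_confident_actives = length(conf_idx),
    params = params[c("n_estimators", "max_depth")],
    confidence = config$confidence, weight_floor = config$weight_floor,
    explainer = unclass(config$explainer)[c("num_features", "num_samples",
                                            "num_explanations")],
    timings_sec = as.list(timing)
  )
  run <- structure(list(
    manifest = manifest, audit = audit, search = search, model = model,
    metrics = metrics, explanations = explanations,
    attributions = attributions, verdicts = verdicts,
    alert_table = alert_tab, validation_ids = rownames(X_va),
    y_validation = y_va, prob_validation = prob_va
  ), class = "toxalert_run")
  if (!is.null(config$output_dir)) .write_run(run, config$output_dir)
  run
}

.write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$audit)) {
    jsonlite::write_json(unclass(run$audit), file.path(dir, "audit.json"),
                         auto_unbox = TRUE, na = "null")
  }
  utils::write.csv(run$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  write_explanations(run$explanations, file.path(dir, "explanations.json"))
  utils::write.csv(as.data.frame(run$alert_table),
                   file.path(dir, "alerts.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(dir)
}

#' @export
print.toxalert_run <- function(x, ...) {
  m <- x$manifest
  cat("<toxalert_run> task ", m$task, ", seed ", m$seed, "\n", sep = "")
  cat("  records: ", m$n_input, " in, ", m$n_train, " train / ",
      m$n_validation, " validation (upsample ", m$upsample_timing,
      " split)\n", sep = "")
  cat("  forest: ", m$params$n_estimators, " trees, depth ",
      m$params$max_depth, "\n", sep = "")
  cat(sprintf("  validation: ROC-AUC %.3f, MCC %.3f, F1 %.3f\n",
              x$metrics$roc_auc, x$metrics$mcc, x$metrics$f1))
  cat("  confident actives explained: ", m$n_confident_actives, "\n", sep = "")
  cat("  alert table: ", nrow(x$alert_table), " fragment(s)",
      if (nrow(x$alert_table)) paste0("; top: ",
                                      x$alert_table$fragment_smiles[1]),
      "\n", sep = "")
  invisible(x)
}
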