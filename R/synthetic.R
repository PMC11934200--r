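#' Default alert substructures planted by the synthetic generator
#'
#' Six functional groups repeatedly implicated as endocrine-disruption
#' toxicophores (thiophosphate, sulfamate ester, anilide, carbamate,
#' sulfamide, thiocyanate). Each row carries the attachable fragment SMILES
#' (written so its first atom bonds to a scaffold carbon) and the SMARTS
#' used to verify its presence.
#'
#' @return data.frame with columns `name`, `fragment`, `smarts`.
#' @export
default_alert_patterns <- function() {
  data.frame(
    name = c("thiophosphate", "sulfamate_ester", "anilide",
             "carbamate", "sulfamide", "thiocyanate"),
    fragment = c("OP(=S)(OC)OC", "OS(=O)(=O)N", "C(=O)Nc1ccccc1",
                 "OC(=O)NC", "NS(=O)(=O)N", "SC#N"),
    smarts = c("OP(=S)(O)O", "OS(=O)(=O)N", "C(=O)Nc1ccccc1",
               "OC(=O)N", "NS(=O)(=O)N", "SC#N"),
    stringsAsFactors = FALSE
  )
}

#' Default inactive carrier scaffolds
#'
#' A hand-picked pool of ~30 simple drug-like carriers. Every scaffold
#' starts with an sp3 carbon so an alert fragment can be attached there by
#' a single bond, and none of them contains any default alert group.
#'
#' @return character vector of SMILES.
#' @export
default_scaffolds <- function() {
  c(
    "CCCCCC", "CCCCCCCC", "CC(C)CCC", "CCC(C)CC", "CCCCCCC",
    "CCOCC", "CCCOC", "CCOCCOC", "CCOC(C)C", "CCCCOC",
    "CCCCO", "CC(C)O", "CC(C)CCO", "CCCCCO", "CCC(C)O",
    "CCN(CC)CC", "CCCN(C)C", "CCCCN", "CC(C)CN", "CCCCCN(C)C",
    "CCSCC", "CCCCS", "CCC(C)=O", "CCCC(C)=O", "CCCCCl",
    "CCc1ccccc1", "CCCc1ccccc1", "CCOc1ccccc1", "CCc1ccc(C)cc1",
    "CC(C)c1ccccc1", "CCc1ccc(O)cc1", "CCc1ccc(F)cc1", "CCc1ccco1",
    "CCc1cccs1"
  )
}

# Benign tails appended at the end of a scaffold to diversify structures.
.DEFAULT_TAILS <- c("", "C", "CC", "O", "CCC")

#' Specification of a synthetic alert-labelled dataset
#'
#' Defines the generative model the pipeline's tests assume: activity is
#' caused by the presence of one planted alert substructure on an otherwise
#' inactive carrier, optionally corrupted by independent label flips.
#'
#' @param n_active number of active molecules (carry one planted alert).
#' @param n_inactive number of inactives (bare scaffolds).
#' @param alert_patterns data.frame like [default_alert_patterns()] (may be
#'   a subset); actives sample uniformly among these.
#' @param scaffold_pool character vector of carrier SMILES.
#' @param label_noise probability in \[0,1\] of flipping each observed label.
#' @param task name of the assay column written to the dataset.
#' @param seed integer seed; the same spec always regenerates the same
#'   dataset.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active = 250, n_inactive = 250,
                           alert_patterns = default_alert_patterns(),
                           scaffold_pool = default_scaffolds(),
                           label_noise = 0, task = "NR-AR", seed = 1L) {
  stopifnot(
    n_active >= 0, n_inactive >= 0,
    label_noise >= 0, label_noise <= 1,
    length(scaffold_pool) > 0,
    is.data.frame(alert_patterns),
    all(c("name", "fragment", "smarts") %in% names(alert_patterns)),
    nrow(alert_patterns) >= 1
  )
  structure(list(
    n_active = as.integer(n_active), n_inactive = as.integer(n_inactive),
    alert_patterns = alert_patterns, scaffold_pool = scaffold_pool,
    label_noise = label_noise, task = task, seed = as.integer(seed),
    tails = .DEFAULT_TAILS
  ), class = "synthetic_spec")
}

# Attach a fragment to the first atom of a scaffold by a single bond, and a
# benign tail at the end. All scaffolds start with an sp3 carbon written as
# a bare "C", so splicing "(<fragment>)" after it is always valid SMILES.
# Tails are skipped on endings that cannot take another single bond
# (halogen, carbonyl oxygen, aromatic heteroatom ring closure).
.decorate <- function(scaffold, fragment = NULL, tail = "") {
  if (grepl("(Cl|F|Br|I|=O|o1|s1|n1)$", scaffold)) tail <- ""
  body <- paste0(scaffold, tail)
  if (is.null(fragment) || !nzchar(fragment)) return(body)
  paste0("C(", fragment, ")", substring(body, 2))
}

#' Generate a synthetic alert-labelled SMILES dataset
#'
#' Actives are scaffolds decorated with one sampled alert fragment;
#' inactives are bare (tailed) scaffolds. Observed labels are then flipped
#' independently with probability `label_noise`. Generated structures are
#' verified: every active must match its planted SMARTS and no inactive may
#' match any alert SMARTS.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_dataset`: list with `records`
#'   (data.frame `mol_id`, `smiles`, one label column named after the task)
#'   and `truth` (data.frame `mol_id`, `true_label`, `observed_label`,
#'   `alert`, `flipped`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pats <- spec$alert_patterns
  bad <- which(is.na(canonical_smiles(pats$fragment)))
  if (length(bad)) {
    stop("invalid alert fragment(s): ", paste(pats$name[bad], collapse = ", "))
  }
  withr::with_seed(spec$seed, {
    n <- spec$n_active + spec$n_inactive
    is_active <- rep(c(TRUE, FALSE), c(spec$n_active, spec$n_inactive))
    scaf <- sample(spec$scaffold_pool, n, replace = TRUE)
    tail <- sample(spec$tails, n, replace = TRUE)
    alert_idx <- ifelse(is_active,
                        sample.int(nrow(pats), n, replace = TRUE), NA)
    smiles <- vapply(seq_len(n), function(i) {
      frag <- if (is_active[i]) pats$fragment[alert_idx[i]] else NULL
      .decorate(scaf[i], frag, tail[i])
    }, character(1))
    flipped <- runif(n) < spec$label_noise
    true_label <- as.integer(is_active)
    observed <- ifelse(flipped, 1L - true_label, true_label)
  })
  # every generated structure must be valid, single-component SMILES
  unparsed <- which(is.na(canonical_smiles(smiles)))
  if (length(unparsed)) {
    stop("generation produced invalid SMILES (scaffold/tail/fragment ",
         "combination): ", paste(head(smiles[unparsed], 3), collapse = ", "))
  }
  # generation-time verification of the planted signal
  for (k in seq_len(nrow(pats))) {
    mine <- which(!is.na(alert_idx) & alert_idx == k)
    if (length(mine)) {
      m <- smarts_matches(smiles[mine], pats$smarts[k])
      if (!all(m %in% TRUE)) {
        stop("attachment chemistry failed for pattern '", pats$name[k],
             "': generated active does not match its SMARTS")
      }
    }
    if (any(spec$n_inactive > 0)) {
      inact <- which(!is_active)
      m <- smarts_matches(smiles[inact], pats$smarts[k])
      if (any(m %in% TRUE)) {
        stop("scaffold pool conflicts with pattern '", pats$name[k],
             "': an undecorated scaffold matches it")
      }
    }
  }
  mol_id <- sprintf("SYN%05d", seq_along(smiles))
  records <- data.frame(mol_id = mol_id, smiles = smiles,
                        stringsAsFactors = FALSE, check.names = FALSE)
  records[[spec$task]] <- observed
  truth <- data.frame(
    mol_id = mol_id, true_label = true_label, observed_label = observed,
    alert = ifelse(is.na(alert_idx), NA_character_, pats$name[alert_idx]),
    flipped = flipped, stringsAsFactors = FALSE
  )
  structure(list(records = records, truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$records), " molecules (",
      sum(x$truth$true_label), " truly active), task '", x$spec$task,
      "', label_noise ", x$spec$label_noise, "\n", sep = "")
  invisible(x)
}

#' Inject curation challenges into a synthetic dataset
#'
#' Appends exact duplicates (same label), conflicting duplicates (flipped
#' label), and rewrites some records as multi-component salts, so curation
#' can be audited against a known ground truth. Base records are chosen
#' among structurally unique molecules, disjoint across the three kinds,
#' so each injection maps to exactly one predictable removal.
#'
#' @param ds a `synthetic_dataset`.
#' @param n_dup,n_conflict,n_salt how many of each to inject.
#' @param seed integer seed.
#' @return the augmented `synthetic_dataset`, with an `injection_audit`
#'   element recording what was injected.
#' @export
inject_duplicates <- function(ds, n_dup = 0, n_conflict = 0, n_salt = 0,
                              seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  rec <- ds$records
  task <- ds$spec$task
  can <- canonical_smiles(rec$smiles)
  uniq <- which(!(duplicated(can) | duplicated(can, fromLast = TRUE)))
  need <- n_dup + n_conflict + n_salt
  if (need > length(uniq)) {
    stop("not enough structurally unique records to inject into (need ",
         need, ", have ", length(uniq), ")")
  }
  withr::with_seed(seed, {
    picked <- sample(uniq, need)
  })
  dup_i <- picked[seq_len(n_dup)]
  con_i <- picked[n_dup + seq_len(n_conflict)]
  salt_i <- picked[n_dup + n_conflict + seq_len(n_salt)]
  extra <- list()
  if (n_dup > 0) {
    d <- rec[dup_i, , drop = FALSE]
    d$mol_id <- paste0(d$mol_id, "-dup")
    extra <- c(extra, list(d))
  }
  if (n_conflict > 0) {
    d <- rec[con_i, , drop = FALSE]
    d$mol_id <- paste0(d$mol_id, "-conflict")
    d[[task]] <- 1L - d[[task]]
    extra <- c(extra, list(d))
  }
  if (n_salt > 0) {
    rec$smiles[salt_i] <- paste0(rec$smiles[salt_i], ".[Na+]")
  }
  out <- ds
  out$records <- do.call(rbind, c(list(rec), extra))
  rownames(out$records) <- NULL
  out$injection_audit <- list(
    n_dup = n_dup, n_conflict = n_conflict, n_salt = n_salt,
    dup_ids = rec$mol_id[dup_i], conflict_ids = rec$mol_id[con_i],
    salt_ids = rec$mol_id[salt_i]
  )
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes the records in the same CSV dialect the pipeline reads
#' (`mol_id`, `smiles`, one column per assay task; blanks for missing), and
#' the generation truth as a JSON sidecar.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "molecules.csv")
  truth <- file.path(dir, "truth.json")
  write_molecule_table(ds$records, csv)
  jsonlite::write_json(ds$truth, truth, dataframe = "rows", na = "null")
  invisible(c(records = csv, truth = truth))
}
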