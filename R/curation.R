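#' Read a molecule table
#'
#' Reads the CSV dialect used throughout: columns `mol_id`, `smiles`, and
#' one binary label column per assay task (blank cells = missing data).
#'
#' @param path CSV file path.
#' @return data.frame with `mol_id`, `smiles` and integer/NA label columns.
#' @export
read_molecule_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  stopifnot(all(c("mol_id", "smiles") %in% names(df)))
  for (col in setdiff(names(df), c("mol_id", "smiles"))) {
    v <- df[[col]]
    v[!nzchar(v)] <- NA
    df[[col]] <- as.integer(v)
  }
  df
}

#' Write a molecule table
#'
#' @param df data.frame with `mol_id`, `smiles` and label columns.
#' @param path output CSV path.
#' @return (invisibly) `path`.
#' @export
write_molecule_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Tanimoto structural-identity score between two molecules
#'
#' Computes the Tanimoto coefficient between the circular fingerprints of
#' two molecules. A coefficient of 1.0 is treated as structural identity
#' for deduplication purposes.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @param radius Morgan radius (default 2).
#' @param n_bits fingerprint width for the identity test (default 2048; the
#'   wider fold keeps false identity collisions negligible).
#' @return similarity in \[0, 1\].
#' @export
canonical_identity <- function(smiles_a, smiles_b, radius = 2L,
                               n_bits = 2048L) {
  mols <- parse_smiles(c(smiles_a, smiles_b))
  fails <- attr(mols, "failures")
  if (nrow(fails)) {
    stop("unparseable SMILES for record(s): ",
         paste(fails$smiles, collapse = ", "))
  }
  tanimoto(fingerprint(mols[[1]], radius, n_bits),
           fingerprint(mols[[2]], radius, n_bits))
}

# Group record indices by structural identity. Default: exact equality of
# canonical SMILES. pairwise = TRUE additionally merges groups whose
# fingerprint Tanimoto is exactly 1 (full-fidelity audit mode).
.identity_groups <- function(smiles, pairwise = FALSE, radius = 2L,
                             n_bits = 2048L) {
  can <- canonical_smiles(smiles)
  grp <- match(can, unique(can))
  if (pairwise) {
    reps <- which(!duplicated(grp))
    if (length(reps) > 1) {
      fps <- lapply(parse_smiles(smiles[reps]), fingerprint,
                    radius = radius, n_bits = n_bits)
      parent <- seq_along(reps)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_along(reps)) {
        for (j in seq_len(i - 1L)) {
          if (tanimoto(fps[[i]], fps[[j]]) == 1) {
            parent[find(i)] <- find(j)
          }
        }
      }
      root <- vapply(seq_along(reps), find, integer(1))
      grp <- match(root[grp], unique(root))
    }
  }
  grp
}

#' Curate one assay task
#'
#' Reproduces the dataset-curation protocol, in this order: (1) drop records
#' with a missing label for the task; (2) drop unparseable SMILES;
#' (3) drop multi-component (salt/complex) records; (4) group structurally
#' identical records (Tanimoto = 1); if any group carries both labels the
#' whole group is dropped, otherwise only the first occurrence in input
#' order is kept. Returns the curated records together with a full audit.
#'
#' @param records data.frame with `mol_id`, `smiles` and a label column
#'   named `task`.
#' @param task name of the label column to curate on.
#' @param pairwise use the O(n^2) fingerprint-Tanimoto identity mode instead
#'   of canonical-SMILES equality (equivalent for identity; slower).
#' @return list with `records` (curated data.frame) and `audit` (an object
#'   of class `curation_audit`).
#' @export
curate_task <- function(records, task, pairwise = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("mol_id", "smiles") %in% names(records)))
  if (!task %in% names(records)) stop("unknown task column: ", task)
  initial <- nrow(records)

  keep <- !is.na(records[[task]])
  no_data <- sum(!keep)
  rec <- records[keep, , drop = FALSE]

  mols <- parse_smiles(rec$smiles, ids = rec$mol_id)
  parse_ok <- !vapply(mols, is.null, logical(1))
  parse_failures <- attr(mols, "failures")
  if (nrow(parse_failures)) {
    warning("dropping ", nrow(parse_failures), " unparseable record(s): ",
            paste(parse_failures$mol_id, collapse = ", "))
  }
  rec <- rec[parse_ok, , drop = FALSE]
  mols <- mols[parse_ok]

  multi <- vapply(mols, function(m) n_components(m) > 1L, logical(1))
  salts_complexes <- sum(multi)
  rec <- rec[!multi, , drop = FALSE]

  unmatched <- 0L; dup_removed <- 0L; dup_groups <- 0L
  if (nrow(rec) > 0) {
    grp <- .identity_groups(rec$smiles, pairwise = pairwise)
    drop <- logical(nrow(rec))
    for (g in unique(grp)) {
      members <- which(grp == g)
      if (length(members) == 1) next
      labs <- unique(rec[[task]][members])
      if (length(labs) > 1) {
        drop[members] <- TRUE
        unmatched <- unmatched + length(members)
      } else {
        drop[members[-1]] <- TRUE
        dup_removed <- dup_removed + length(members) - 1L
        dup_groups <- dup_groups + 1L
      }
    }
    rec <- rec[!drop, , drop = FALSE]
  }
  if (nrow(rec) == 0) warning("curation removed every record for task ", task)

  audit <- structure(list(
    task = task,
    initial = initial,
    no_data = no_data,
    parse_failures = nrow(parse_failures),
    parse_failure_ids = parse_failures$mol_id,
    salts_complexes = salts_complexes,
    unmatched_labels = unmatched,
    duplicates_removed = dup_removed,
    duplicate_groups = dup_groups,
    final = nrow(rec),
    order = c("no_data", "parse_failures", "salts_complexes",
              "unmatched_labels", "duplicates_removed")
  ), class = "curation_audit")
  # conservation identity: removals + final = initial
  stopifnot(audit$initial - audit$no_data - audit$parse_failures -
              audit$salts_complexes - audit$unmatched_labels -
              audit$duplicates_removed == audit$final)
  rownames(rec) <- NULL
  list(records = rec, audit = audit)
}

#' @export
print.curation_audit <- function(x, ...) {
  cat("<curation_audit> task ", x$task, "\n", sep = "")
  cat(sprintf("  initial              %6d\n", x$initial))
  cat(sprintf("  no data              %6d\n", x$no_data))
  cat(sprintf("  parse failures       %6d\n", x$parse_failures))
  cat(sprintf("  salts/complexes      %6d\n", x$salts_complexes))
  cat(sprintf("  unmatched labels     %6d\n", x$unmatched_labels))
  cat(sprintf("  duplicates removed   %6d (%d groups)\n",
              x$duplicates_removed, x$duplicate_groups))
  cat(sprintf("  final                %6d\n", x$final))
  invisible(x)
}

#' Curate several tasks of one molecule table
#'
#' @param records data.frame with `mol_id`, `smiles` and label columns.
#' @param tasks character vector of task columns (default: all label
#'   columns present).
#' @param pairwise see [curate_task()].
#' @return list with one `curate_task()` result per task, plus an
#'   `audit_table` data.frame shaped like a per-task accounting table.
#' @export
curate_all <- function(records, tasks = NULL, pairwise = FALSE) {
  if (is.null(tasks)) tasks <- setdiff(names(records), c("mol_id", "smiles"))
  out <- lapply(tasks, function(t) curate_task(records, t, pairwise = pairwise))
  names(out) <- tasks
  list(tasks = out, audit_table = audit_table(lapply(out, `[[`, "audit")))
}

#' Tabulate curation audits
#'
#' @param audits list of `curation_audit` objects.
#' @return data.frame, one row per task, with the accounting columns.
#' @export
audit_table <- function(audits) {
  do.call(rbind, lapply(audits, function(a) {
    data.frame(
      task = a$task, initial = a$initial, no_data = a$no_data,
      parse_failures = a$parse_failures, salts_complexes = a$salts_complexes,
      unmatched_labels = a$unmatched_labels,
      duplicates_removed = a$duplicates_removed,
      duplicate_groups = a$duplicate_groups, final = a$final,
      stringsAsFactors = FALSE
    )
  }))
}
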