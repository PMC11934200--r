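#' Filter explanations down to confidently predicted true disruptors
#'
#' Keeps molecules whose true label is 1, whose predicted label is 1, and
#' whose model probability is at least `threshold` (default 0.8). Only
#' these molecules feed the alert table, so every aggregated fragment comes
#' from a correctly and confidently predicted active.
#'
#' @param explanations named list of `local_explanation` objects.
#' @param y_true named binary vector (or vector aligned to the list).
#' @param threshold confidence threshold on the class-1 probability.
#' @param predict_threshold probability cutoff defining the predicted label
#'   (default 0.5).
#' @return the filtered sub-list of explanations.
#' @export
select_confident_actives <- function(explanations, y_true, threshold = 0.8,
                                     predict_threshold = 0.5) {
  stopifnot(length(explanations) == length(y_true))
  prob <- vapply(explanations, `[[`, numeric(1), "model_probability")
  keep <- (y_true == 1) & (prob >= predict_threshold) & (prob >= threshold)
  explanations[keep]
}

#' Map explanation weights back to molecular fragments
#'
#' For each weighted bit that is active in the molecule, emits one
#' attribution per recorded bit environment: the fragment's atom/bond
#' indices, its canonical SMILES, and the bit's surrogate weight. Bits in
#' the explanation that are not active in this molecule contribute nothing;
#' a colliding bit with several environments yields several attributions
#' sharing one weight.
#'
#' @param explanation a `local_explanation`.
#' @param fp the molecule's `bit_fingerprint`.
#' @return data.frame of class `fragment_attribution` with columns
#'   `mol_id`, `bit`, `fragment_smiles`, `weight`, `center`, `radius`, and
#'   list-columns `atom_indices`, `bond_indices`.
#' @export
attribute_fragments <- function(explanation, fp) {
  stopifnot(inherits(explanation, "local_explanation"),
            inherits(fp, "bit_fingerprint"))
  w <- explanation$weights
  w <- w[w$bit %in% fp$bits, , drop = FALSE]
  empty <- data.frame(
    mol_id = character(0), bit = integer(0), fragment_smiles = character(0),
    weight = numeric(0), center = integer(0), radius = integer(0)
  )
  empty$atom_indices <- list(); empty$bond_indices <- list()
  if (nrow(w) == 0) {
    class(empty) <- c("fragment_attribution", class(empty))
    return(empty)
  }
  rows <- list()
  frag_jobs <- list()
  for (r in seq_len(nrow(w))) {
    env <- fp$environments[[as.character(w$bit[r])]]
    for (k in seq_len(nrow(env))) {
      sub <- .environment_subgraph(fp$mol, env$atom[k], env$radius[k])
      frag_jobs[[length(frag_jobs) + 1L]] <-
        list(mol = fp$mol, atoms = sub$atoms, bonds = sub$bonds)
      rows[[length(rows) + 1L]] <- list(
        bit = w$bit[r], weight = w$weight[r],
        center = env$atom[k], radius = env$radius[k],
        atoms = sub$atoms, bonds = sub$bonds
      )
    }
  }
  frag_smi <- fragment_smiles_batch(frag_jobs)
  out <- data.frame(
    mol_id = rep(if (is.null(explanation$mol_id)) NA_character_ else
      explanation$mol_id, length(rows)),
    bit = vapply(rows, `[[`, integer(1), "bit"),
    fragment_smiles = frag_smi,
    weight = vapply(rows, `[[`, numeric(1), "weight"),
    center = vapply(rows, `[[`, integer(1), "center"),
    radius = vapply(rows, `[[`, integer(1), "radius"),
    stringsAsFactors = FALSE
  )
  out$atom_indices <- lapply(rows, `[[`, "atoms")
  out$bond_indices <- lapply(rows, `[[`, "bonds")
  class(out) <- c("fragment_attribution", class(out))
  out
}

#' Disruptor verdict for one molecule
#'
#' Separately sums the positive and negative attribution weights; the
#' molecule is classified a disruptor iff the positive sum strictly exceeds
#' the negative sum (an empty attribution list is a non-disruptor).
#'
#' @param attributions a `fragment_attribution` data.frame for one molecule.
#' @return object of class `molecule_verdict` with `positive_sum`,
#'   `negative_sum` and `verdict`.
#' @export
molecule_verdict <- function(attributions) {
  w <- attributions$weight
  pos <- sum(pmax(w, 0))
  neg <- sum(pmax(-w, 0))
  structure(list(
    mol_id = if (nrow(attributions)) attributions$mol_id[1] else NA_character_,
    positive_sum = pos, negative_sum = neg,
    verdict = if (pos > neg) "disruptor" else "non-disruptor"
  ), class = "molecule_verdict")
}

#' @export
print.molecule_verdict <- function(x, ...) {
  cat("<molecule_verdict> ", x$mol_id, ": ", x$verdict,
      sprintf(" (+%.3f / -%.3f)\n", x$positive_sum, x$negative_sum), sep = "")
  invisible(x)
}

#' Aggregate attributions into a ranked toxic-alert table
#'
#' Drops attributions with weight <= `weight_floor` (strictly greater
#' survives), deduplicates per (molecule, fragment, bit), and groups by
#' canonical fragment SMILES. `occurrences` counts distinct
#' (molecule, fragment) pairs so a bit collision cannot double-count one
#' motif in one molecule; `total_weight` sums the surviving weights. The
#' table is sorted by total weight descending, ties broken by occurrences
#' then fragment string.
#'
#' @param attributions a `fragment_attribution` data.frame pooled over the
#'   confidently predicted actives.
#' @param weight_floor minimum weight (default 0.1; exclusive).
#' @param floor_on apply the floor to individual attributions
#'   (`"attribution"`, default) or to aggregated totals (`"total"`).
#' @return data.frame of class `alert_table` with columns
#'   `fragment_smiles`, `occurrences`, `total_weight`.
#' @export
aggregate_alerts <- function(attributions, weight_floor = 0.1,
                             floor_on = c("attribution", "total")) {
  floor_on <- match.arg(floor_on)
  att <- as.data.frame(attributions)[, c("mol_id", "bit", "fragment_smiles",
                                         "weight")]
  att <- att[!is.na(att$fragment_smiles), , drop = FALSE]
  if (floor_on == "attribution") {
    att <- att[att$weight > weight_floor, , drop = FALSE]
  }
  if (nrow(att) == 0) {
    out <- data.frame(fragment_smiles = character(0),
                      occurrences = integer(0), total_weight = numeric(0))
    class(out) <- c("alert_table", class(out))
    return(out)
  }
  # one weight per (molecule, fragment, bit); symmetric environments of one
  # bit mapping to the same fragment collapse to a single contribution
  att <- att[!duplicated(att[, c("mol_id", "fragment_smiles", "bit")]), ,
             drop = FALSE]
  pair <- aggregate(weight ~ mol_id + fragment_smiles, data = att, FUN = sum)
  out <- aggregate(weight ~ fragment_smiles, data = pair, FUN = sum)
  names(out)[names(out) == "weight"] <- "total_weight"
  occ <- aggregate(mol_id ~ fragment_smiles, data = pair,
                   FUN = function(v) length(unique(v)))
  out$occurrences <- occ$mol_id[match(out$fragment_smiles,
                                      occ$fragment_smiles)]
  if (floor_on == "total") {
    out <- out[out$total_weight > weight_floor, , drop = FALSE]
  }
  out <- out[out$total_weight > 0, , drop = FALSE]
  out <- out[order(-out$total_weight, -out$occurrences, out$fragment_smiles), ,
             drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("fragment_smiles", "occurrences", "total_weight")]
  class(out) <- c("alert_table", class(out))
  out
}

#' @export
print.alert_table <- function(x, ...) {
  cat("<alert_table> ", nrow(x), " fragment(s)\n", sep = "")
  if (nrow(x)) print.data.frame(head(x, 10), row.names = FALSE)
  invisible(x)
}

#' Highlight descriptor for a molecule's attributed fragments
#'
#' Collects the atom/bond index sets of each attributed fragment, plus their
#' union, in a serializable form any depiction backend can consume. No
#' drawing happens here.
#'
#' @param attributions a `fragment_attribution` data.frame for one molecule.
#' @return list with `fragments` (per-fragment id, atoms, bonds, weight) and
#'   the union `atoms`/`bonds` sets.
#' @export
render_highlights <- function(attributions) {
  frags <- lapply(seq_len(nrow(attributions)), function(i) {
    list(fragment_smiles = attributions$fragment_smiles[i],
         bit = attributions$bit[i],
         weight = attributions$weight[i],
         atoms = attributions$atom_indices[[i]],
         bonds = attributions$bond_indices[[i]])
  })
  list(
    mol_id = if (nrow(attributions)) attributions$mol_id[1] else NA_character_,
    fragments = frags,
    atoms = sort(unique(unlist(lapply(frags, `[[`, "atoms")))),
    bonds = sort(unique(unlist(lapply(frags, `[[`, "bonds"))))
  )
}
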