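# Deterministic integer hash of an integer vector, folded into [0, 2^31-2].
# Plain polynomial rolling hash; all arithmetic stays below 2^53 so doubles
# are exact.
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + x + 7) %% 2147483647
  h
}

# Initial Morgan invariant per atom: element, charge, heavy degree,
# implicit H count, ring membership.
.atom_invariants <- function(mol) {
  vapply(seq_len(mol$n_atoms), function(i) {
    .hash_ints(c(
      mol$atomic_numbers[i],
      mol$charges[i] + 10L,
      length(mol$neighbors[[i]]),
      mol$n_h[i],
      as.integer(mol$atom_in_ring[i])
    ))
  }, numeric(1))
}

# Bonds within `radius` BFS steps of a center atom (the ECFP environment),
# plus the atoms they span.
.environment_subgraph <- function(mol, center, radius) {
  if (radius == 0L || !length(mol$neighbors[[center]])) {
    return(list(atoms = center, bonds = integer(0)))
  }
  dist <- rep(Inf, mol$n_atoms)
  dist[center] <- 0
  frontier <- center
  bonds <- integer(0)
  for (r in seq_len(radius)) {
    nxt <- integer(0)
    for (a in frontier) {
      nb <- mol$neighbors[[a]]
      bd <- mol$neighbor_bonds[[a]]
      bonds <- c(bonds, bd)
      newly <- nb[dist[nb] > r]
      dist[newly] <- r
      nxt <- c(nxt, newly)
    }
    frontier <- unique(nxt)
    if (!length(frontier)) break
  }
  bonds <- sort(unique(bonds))
  atoms <- sort(unique(c(center, as.vector(mol$bonds[bonds, 1:2]))))
  list(atoms = atoms, bonds = bonds)
}

#' Extended-connectivity fingerprint with environment bookkeeping
#'
#' Computes a folded circular (Morgan/ECFP) fingerprint of a molecule and
#' records, for every active bit, the (center atom, radius) environments
#' that set it. The environment map is what later allows surrogate-model
#' weights on bits to be traced back to concrete substructures.
#'
#' Environments whose bond sets coincide with an already-emitted environment
#' at the same or a smaller radius are deduplicated, and an atom whose
#' neighborhood stops growing stops emitting, matching standard ECFP
#' behaviour (a lone atom contributes exactly one radius-0 bit).
#'
#' @param mol a `molgraph` (from [parse_smiles()]) or a SMILES string.
#' @param radius maximum environment radius in bonds (default 2, the
#'   ECFP4-equivalent community standard).
#' @param n_bits folded fingerprint width (default 1024).
#' @return an object of class `bit_fingerprint`: list with `bits` (sorted
#'   0-based indices of active bits), `n_bits`, `radius`, and
#'   `environments`, a named list mapping each active bit (as character) to
#'   a data.frame with columns `atom` and `radius`.
#' @export
fingerprint <- function(mol, radius = 2L, n_bits = 1024L) {
  if (is.character(mol)) {
    m <- parse_smiles(mol)[[1]]
    if (is.null(m)) stop("unparseable SMILES: ", mol)
    mol <- m
  }
  stopifnot(inherits(mol, "molgraph"))
  n <- mol$n_atoms
  inv <- .atom_invariants(mol)
  envs <- list()      # emitted environments: bit -> data.frame(atom, radius)
  seen_bondsets <- character(0)
  prev_bondset <- rep("", n)
  emit <- function(bit, atom, rad) {
    key <- as.character(bit)
    envs[[key]] <<- rbind(envs[[key]], data.frame(atom = atom, radius = rad))
  }
  for (i in seq_len(n)) emit(inv[i] %% n_bits, i, 0L)
  for (r in seq_len(radius)) {
    new_inv <- numeric(n)
    for (i in seq_len(n)) {
      nb <- mol$neighbors[[i]]
      if (length(nb)) {
        pairs <- cbind(mol$neighbor_orders[[i]], inv[nb])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        new_inv[i] <- .hash_ints(c(r, inv[i], as.vector(t(pairs))))
      } else {
        new_inv[i] <- inv[i]
      }
    }
    for (i in seq_len(n)) {
      env <- .environment_subgraph(mol, i, r)
      key <- paste(env$bonds, collapse = ",")
      if (key == prev_bondset[i]) next          # neighborhood stopped growing
      prev_bondset[i] <- key
      if (key %in% seen_bondsets) next          # identical environment emitted
      seen_bondsets <- c(seen_bondsets, key)
      emit(new_inv[i] %% n_bits, i, r)
    }
    inv <- new_inv
  }
  bits <- sort(as.integer(names(envs)))
  structure(list(
    bits = bits,
    n_bits = as.integer(n_bits),
    radius = as.integer(radius),
    environments = envs[as.character(bits)],
    mol = mol
  ), class = "bit_fingerprint")
}

#' @export
print.bit_fingerprint <- function(x, ...) {
  cat("<bit_fingerprint> ", length(x$bits), "/", x$n_bits,
      " active bits (radius ", x$radius, ")\n", sep = "")
  invisible(x)
}

#' Fragments responsible for a fingerprint bit
#'
#' Returns one descriptor per recorded environment of an active bit: the
#' atom and bond indices of the subgraph within the environment radius of
#' the center atom, plus its canonical fragment SMILES. A bit set by several
#' distinct environments (a folding collision, or symmetry) yields several
#' descriptors.
#'
#' @param fp a `bit_fingerprint`.
#' @param bit 0-based bit index.
#' @return a list of descriptors (`atom_indices`, `bond_indices`,
#'   `fragment_smiles`, `center`, `radius`); empty list if the bit is not
#'   active in this molecule.
#' @export
fragment_for_bit <- function(fp, bit) {
  stopifnot(inherits(fp, "bit_fingerprint"))
  env <- fp$environments[[as.character(bit)]]
  if (is.null(env)) return(list())
  subs <- lapply(seq_len(nrow(env)), function(k) {
    .environment_subgraph(fp$mol, env$atom[k], env$radius[k])
  })
  frag_smi <- fragment_smiles_batch(lapply(subs, function(s)
    list(mol = fp$mol, atoms = s$atoms, bonds = s$bonds)))
  lapply(seq_len(nrow(env)), function(k) {
    list(
      atom_indices = subs[[k]]$atoms,
      bond_indices = subs[[k]]$bonds,
      fragment_smiles = frag_smi[k],
      center = env$atom[k],
      radius = env$radius[k]
    )
  })
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over the active-bit sets. A coefficient of
#' 1.0 is treated as structural identity during deduplication.
#'
#' @param a,b `bit_fingerprint` objects, or plain integer vectors of active
#'   bit indices.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  ba <- if (inherits(a, "bit_fingerprint")) a$bits else as.integer(a)
  bb <- if (inherits(b, "bit_fingerprint")) b$bits else as.integer(b)
  u <- length(union(ba, bb))
  if (u == 0) return(1)
  length(intersect(ba, bb)) / u
}

#' Binary feature matrix of fingerprints
#'
#' Fingerprints a vector of SMILES into an n x n_bits 0/1 matrix with
#' molecule ids as row names and `bit0 ... bit{n_bits-1}` as column names.
#'
#' @param smiles character vector of SMILES.
#' @param ids row identifiers (defaults to names or index).
#' @param radius,n_bits as in [fingerprint()].
#' @param keep_fingerprints also return the `bit_fingerprint` objects
#'   (needed later for fragment attribution).
#' @return a list with `X` (the matrix) and, if requested, `fingerprints`;
#'   unparseable SMILES are dropped and reported in the `failures`
#'   attribute of `X`.
#' @export
feature_matrix <- function(smiles, ids = NULL, radius = 2L, n_bits = 1024L,
                           keep_fingerprints = FALSE) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else as.character(seq_along(smiles))
  mols <- parse_smiles(smiles, ids = ids)
  ok <- !vapply(mols, is.null, logical(1))
  fps <- lapply(mols[ok], fingerprint, radius = radius, n_bits = n_bits)
  X <- matrix(0L, nrow = sum(ok), ncol = n_bits,
              dimnames = list(ids[ok], paste0("bit", seq_len(n_bits) - 1L)))
  for (i in seq_along(fps)) X[i, fps[[i]]$bits + 1L] <- 1L
  attr(X, "failures") <- attr(mols, "failures")
  if (keep_fingerprints) {
    names(fps) <- ids[ok]
    list(X = X, fingerprints = fps)
  } else {
    list(X = X)
  }
}
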