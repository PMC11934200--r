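#' @importFrom stats runif setNames aggregate sd quantile cor predict
#' @importFrom utils read.csv write.csv head
NULL

# Atomic numbers for the organic subset we expect in SMILES input.
.ATOMIC_NUMBERS <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Zn = 30, Br = 35, I = 53
)

# Default valences used to infer implicit hydrogen counts from a kekulized
# heavy-atom graph. Multi-valent elements list all common states; the
# smallest one that accommodates the bond-order sum is used.
.VALENCES <- list(
  H = 1, B = 3, C = 4, N = c(3, 5), O = 2, F = 1, Si = 4,
  P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("the 'obabel' executable is required but was not found on PATH")
  p
}

# Run obabel on a batch of input lines, returning output lines.
# `-e` keeps obabel going past unparseable records.
.ob_run <- function(lines, args) {
  fin <- tempfile(fileext = ".in")
  fout <- tempfile(fileext = ".out")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(lines, fin)
  status <- suppressWarnings(system2(
    .obabel_path(), c(args(fin, fout)),
    stdout = FALSE, stderr = FALSE
  ))
  if (!file.exists(fout)) return(character(0))
  readLines(fout, warn = FALSE)
}

# Parse "SMILES<tab-or-space>title" output lines into a title -> smiles map.
.ob_titled_smiles <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character(0))
  sm <- sub("[ \t].*$", "", lines)
  ti <- sub("^[^ \t]+[ \t]+", "", lines)
  ti[ti == lines] <- ""  # no title present
  setNames(sm, ti)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Canonical SMILES are used as
#' the primary structural-identity key during curation and to make
#' fingerprints independent of how the input SMILES happened to be written.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where a string could
#'   not be parsed.
#' @export
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  lines <- paste(smiles[idx], seq_along(idx))
  res <- .ob_run(lines, function(fin, fout)
    c("-ismi", fin, "-ocan", "-O", fout, "-e"))
  map <- .ob_titled_smiles(res)
  hit <- match(as.character(seq_along(idx)), names(map))
  out[idx] <- unname(map[hit])
  out
}

# Convert SMILES to V2000 molfile text; returns list of per-record character
# vectors, NULL where parsing failed. Titles carry the input index.
.smiles_to_molfiles <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  lines <- paste(smiles[idx], seq_along(idx))
  res <- .ob_run(lines, function(fin, fout)
    c("-ismi", fin, "-osdf", "-O", fout, "-e"))
  if (!length(res)) return(out)
  rec_end <- which(res == "$$$$")
  start <- c(1L, head(rec_end, -1) + 1L)
  for (k in seq_along(rec_end)) {
    rec <- res[start[k]:(rec_end[k] - 1L)]
    title <- suppressWarnings(as.integer(rec[1]))
    if (!is.na(title) && title >= 1 && title <= length(idx))
      out[[idx[title]]] <- rec
  }
  out
}

# Decode one V2000 molfile (character vector) into a molecular graph.
.molfile_to_graph <- function(rec) {
  counts <- rec[4]
  n_at <- as.integer(substr(counts, 1, 3))
  n_bd <- as.integer(substr(counts, 4, 6))
  if (is.na(n_at) || n_at < 1) return(NULL)
  at_lines <- rec[5:(4 + n_at)]
  elements <- trimws(substr(at_lines, 32, 34))
  old_chg <- suppressWarnings(as.integer(substr(at_lines, 37, 39)))
  charges <- integer(n_at)
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  for (i in seq_len(n_at)) {
    cc <- old_chg[i]
    if (!is.na(cc) && cc > 0 && as.character(cc) %in% names(code_map))
      charges[i] <- code_map[[as.character(cc)]]
  }
  if (n_bd > 0) {
    bd_lines <- rec[(5 + n_at):(4 + n_at + n_bd)]
    bonds <- cbind(
      a1 = as.integer(substr(bd_lines, 1, 3)),
      a2 = as.integer(substr(bd_lines, 4, 6)),
      order = as.integer(substr(bd_lines, 7, 9))
    )
  } else {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("a1", "a2", "order")))
  }
  # "M  CHG" property lines override the legacy atom-block charge codes
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines)) {
    charges <- integer(n_at)
    for (cl in chg_lines) {
      toks <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "[ ]+")[[1]])
      nent <- toks[1]
      for (e in seq_len(nent)) {
        charges[toks[2 * e]] <- toks[2 * e + 1]
      }
    }
  }
  .build_molgraph(elements, charges, bonds)
}

.build_molgraph <- function(elements, charges, bonds, smiles = NA_character_) {
  n <- length(elements)
  nbrs <- vector("list", n)
  nbr_orders <- vector("list", n)
  nbr_bonds <- vector("list", n)
  for (i in seq_len(n)) {
    nbrs[[i]] <- integer(0); nbr_orders[[i]] <- integer(0); nbr_bonds[[i]] <- integer(0)
  }
  nb <- nrow(bonds)
  for (b in seq_len(nb)) {
    a1 <- bonds[b, 1]; a2 <- bonds[b, 2]; o <- bonds[b, 3]
    nbrs[[a1]] <- c(nbrs[[a1]], a2); nbr_orders[[a1]] <- c(nbr_orders[[a1]], o)
    nbr_bonds[[a1]] <- c(nbr_bonds[[a1]], b)
    nbrs[[a2]] <- c(nbrs[[a2]], a1); nbr_orders[[a2]] <- c(nbr_orders[[a2]], o)
    nbr_bonds[[a2]] <- c(nbr_bonds[[a2]], b)
  }
  # implicit hydrogens from default valences, adjusted for formal charge
  n_h <- integer(n)
  for (i in seq_len(n)) {
    val <- .VALENCES[[elements[i]]]
    if (is.null(val)) { n_h[i] <- 0L; next }
    bsum <- sum(nbr_orders[[i]])
    adj <- val
    ch <- charges[i]
    if (ch != 0) {
      if (elements[i] %in% c("N", "P")) adj <- val + ch
      else adj <- val + ifelse(ch < 0, ch, -ch)
    }
    adj <- adj[adj >= bsum]
    n_h[i] <- if (length(adj)) min(adj) - bsum else 0L
  }
  # ring membership: a bond is in a ring iff it is not a bridge
  bond_in_ring <- logical(nb)
  atom_in_ring <- logical(n)
  comp <- seq_len(n)
  if (nb > 0) {
    g <- igraph::make_graph(edges = as.vector(t(bonds[, 1:2, drop = FALSE])),
                            n = n, directed = FALSE)
    br <- igraph::bridges(g)
    bond_in_ring <- !(seq_len(nb) %in% as.integer(br))
    for (b in which(bond_in_ring)) {
      atom_in_ring[bonds[b, 1]] <- TRUE
      atom_in_ring[bonds[b, 2]] <- TRUE
    }
    comp <- igraph::components(g)$membership
  }
  structure(list(
    smiles = smiles,
    n_atoms = n,
    elements = elements,
    atomic_numbers = unname(.ATOMIC_NUMBERS[elements]),
    charges = charges,
    bonds = bonds,
    neighbors = nbrs,
    neighbor_orders = nbr_orders,
    neighbor_bonds = nbr_bonds,
    n_h = n_h,
    atom_in_ring = atom_in_ring,
    bond_in_ring = bond_in_ring,
    component = comp
  ), class = "molgraph")
}

#' Parse SMILES into molecular graphs
#'
#' Parses SMILES strings into heavy-atom molecular graphs (kekulized bond
#' orders, formal charges, implicit hydrogen counts, ring membership).
#' Inputs are canonicalized first so that different spellings of the same
#' molecule yield identical graphs.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers carried into error messages.
#' @param canonicalize canonicalize before building the graph (default TRUE).
#' @return a list of `molgraph` objects, with `NULL` for unparseable inputs;
#'   the `failures` attribute lists the offending indices and ids.
#' @export
parse_smiles <- function(smiles, ids = NULL, canonicalize = TRUE) {
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  can <- if (canonicalize) canonical_smiles(smiles) else smiles
  mfs <- .smiles_to_molfiles(can)
  out <- vector("list", length(smiles))
  for (i in seq_along(mfs)) {
    if (is.null(mfs[[i]])) next
    g <- .molfile_to_graph(mfs[[i]])
    if (!is.null(g)) { g$smiles <- can[i]; out[[i]] <- g }
  }
  failed <- which(vapply(out, is.null, logical(1)))
  attr(out, "failures") <- data.frame(
    index = failed, mol_id = ids[failed], smiles = smiles[failed],
    stringsAsFactors = FALSE
  )
  out
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, ": ", x$n_atoms, " heavy atoms, ",
      nrow(x$bonds), " bonds, ", max(x$component), " component(s)\n", sep = "")
  invisible(x)
}

#' Number of disconnected components in a molecule
#'
#' @param mol a `molgraph`.
#' @return integer count of connected components.
#' @export
n_components <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  max(mol$component)
}

#' Detect multi-component (salt/complex) SMILES
#'
#' A record whose SMILES encodes more than one disconnected fragment
#' (e.g. a drug plus its counter-ion) is treated as a salt/complex and is
#' removed during curation rather than salt-stripped.
#'
#' @param smiles character vector of SMILES.
#' @return logical vector; `NA` for unparseable input.
#' @export
is_multicomponent <- function(smiles) {
  mols <- parse_smiles(smiles)
  vapply(mols, function(m) {
    if (is.null(m)) NA else n_components(m) > 1L
  }, logical(1))
}

#' Match a SMARTS pattern against SMILES
#'
#' Batched substructure matching through OpenBabel. Used to verify planted
#' alert substructures in synthetic data and to screen scaffolds.
#'
#' @param smiles character vector of SMILES.
#' @param smarts a single SMARTS pattern.
#' @return logical vector (`NA` for unparseable SMILES).
#' @export
smarts_matches <- function(smiles, smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1)
  out <- rep(NA, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  lines <- paste(smiles[idx], seq_along(idx))
  # which inputs parse at all (those that reach the output with -e)
  parsed <- .ob_run(lines, function(fin, fout)
    c("-ismi", fin, "-osmi", "-O", fout, "-e"))
  seen <- names(.ob_titled_smiles(parsed))
  hit <- .ob_run(lines, function(fin, fout)
    c("-ismi", fin, "-osmi", "-O", fout, "-e", "-s", shQuote(smarts)))
  matched <- names(.ob_titled_smiles(hit))
  out[idx] <- NA
  out[idx[as.integer(seen)]] <- FALSE
  out[idx[as.integer(matched)]] <- TRUE
  out
}

# Compose a V2000 molfile for an atom/bond subset of a molgraph.
.subgraph_molfile <- function(mol, atoms, bonds, title = "frag") {
  atoms <- sort(unique(atoms))
  remap <- setNames(seq_along(atoms), atoms)
  hdr <- c(title, " toxalert", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    length(atoms), length(bonds))
  at <- vapply(atoms, function(a) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, mol$elements[a])
  }, character(1))
  bd <- vapply(bonds, function(b) {
    sprintf("%3d%3d%3d  0  0  0  0",
            remap[[as.character(mol$bonds[b, 1])]],
            remap[[as.character(mol$bonds[b, 2])]],
            mol$bonds[b, 3])
  }, character(1))
  chg <- which(mol$charges[atoms] != 0)
  chg_lines <- character(0)
  if (length(chg)) {
    chg_lines <- vapply(chg, function(k) {
      sprintf("M  CHG  1 %3d %3d", k, mol$charges[atoms[k]])
    }, character(1))
  }
  c(hdr, counts, at, if (length(bonds)) bd, chg_lines, "M  END", "$$$$")
}

#' Canonical SMILES for molecular subgraphs
#'
#' Converts atom/bond subsets of parsed molecules into canonical fragment
#' SMILES (one OpenBabel call for the whole batch). Bond orders are taken
#' from the kekulized parent, so partially extracted aromatic environments
#' appear in kekule form; dangling bonds are not capped.
#'
#' @param fragments a list; each element a list with `mol` (a `molgraph`),
#'   `atoms` (atom indices) and `bonds` (bond indices).
#' @return character vector of canonical fragment SMILES (NA on failure).
#' @export
fragment_smiles_batch <- function(fragments) {
  if (!length(fragments)) return(character(0))
  recs <- unlist(lapply(seq_along(fragments), function(i) {
    f <- fragments[[i]]
    .subgraph_molfile(f$mol, f$atoms, f$bonds, title = as.character(i))
  }))
  res <- .ob_run(recs, function(fin, fout)
    c("-isdf", fin, "-ocan", "-O", fout, "-e"))
  map <- .ob_titled_smiles(res)
  out <- rep(NA_character_, length(fragments))
  ti <- suppressWarnings(as.integer(names(map)))
  ok <- !is.na(ti) & ti >= 1 & ti <= length(fragments)
  out[ti[ok]] <- unname(map[ok])
  out
}

#' Graph-based substructure containment
#'
#' Tests whether `query` occurs as a (not necessarily induced) subgraph of
#' `parent`, matching atoms by element. Bond orders can optionally be
#' matched too; by default they are ignored so that kekule-form fragments
#' extracted from aromatic rings still match their parent.
#'
#' @param parent a `molgraph` or SMILES string.
#' @param query a `molgraph` or SMILES string.
#' @param match_bond_order also require bond orders to agree.
#' @return logical.
#' @export
has_substructure <- function(parent, query, match_bond_order = FALSE) {
  as_mol <- function(x) {
    if (inherits(x, "molgraph")) return(x)
    m <- parse_smiles(x)[[1]]
    if (is.null(m)) stop("unparseable SMILES: ", x)
    m
  }
  p <- as_mol(parent); q <- as_mol(query)
  if (q$n_atoms > p$n_atoms) return(FALSE)
  gp <- igraph::make_graph(
    edges = as.vector(t(p$bonds[, 1:2, drop = FALSE])), n = p$n_atoms,
    directed = FALSE)
  gq <- igraph::make_graph(
    edges = as.vector(t(q$bonds[, 1:2, drop = FALSE])), n = q$n_atoms,
    directed = FALSE)
  # graph.subisomorphic.vf2 takes (target, pattern); colors 1/2 follow that
  if (match_bond_order) {
    igraph::subgraph_isomorphic(
      gq, gp, method = "vf2",
      vertex.color1 = p$atomic_numbers, vertex.color2 = q$atomic_numbers,
      edge.color1 = p$bonds[, 3], edge.color2 = q$bonds[, 3])
  } else {
    igraph::subgraph_isomorphic(
      gq, gp, method = "vf2",
      vertex.color1 = p$atomic_numbers, vertex.color2 = q$atomic_numbers)
  }
}
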