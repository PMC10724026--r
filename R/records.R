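# Domain containers: LigandRecord and PocketRecord.
#
# Pair-indexed matrices throughout the package are flattened row-major:
# row (i-1)*ncol + k holds pair (i, k).

#' Flattened pair-row index
#'
#' Row index of pair `(i, k)` in a flattened pair tensor with `nc` columns.
#' @param i,k Atom indices.
#' @param nc Number of columns (second-axis size) of the pair grid.
#' @return Integer row index.
#' @export
pair_row <- function(i, k, nc) (i - 1L) * nc + k

#' Construct a ligand record
#'
#' Holds a small molecule over heavy atoms only: its bond graph, one-hot
#' atom/bond features, one or more 3D conformers and, optionally, the bound
#' (holo) pose and an affinity label on the pK scale (-log10 of a binding
#' constant).
#'
#' @param mol Internal molecule structure (see [pd_mol()]).
#' @param conformers List of M x 3 coordinate matrices (Angstrom); may be
#'   empty at construction but must be non-empty at inference.
#' @param holo_coords Optional M x 3 matrix of the bound pose.
#' @param affinity Optional numeric pK label.
#' @return An object of class `ligand_record` with elements `mol`,
#'   `atom_count`, `atom_features` (M x 28), `bond_features`
#'   ((M*M) x 6, flattened row-major, zero rows for unbonded pairs),
#'   `conformers`, `holo_coords`, `affinity`.
#' @export
ligand_record <- function(mol, conformers = list(), holo_coords = NULL,
                          affinity = NULL) {
  M <- length(mol$elements)
  if (M < 2L) stop("ligand must have at least 2 heavy atoms")
  if (any(mol$elements %in% c("H", "D"))) stop("hydrogens must be stripped")
  feats <- featurize(mol)
  bf <- feats$bond_features
  # symmetry invariant: e_ik == e_ki
  perm <- chan_tperm(M, M)
  stopifnot(max(abs(bf - bf[perm, , drop = FALSE])) == 0)
  for (cf in conformers) {
    stopifnot(is.matrix(cf), nrow(cf) == M, ncol(cf) == 3L, all(is.finite(cf)))
  }
  if (!is.null(holo_coords)) {
    stopifnot(nrow(holo_coords) == M, ncol(holo_coords) == 3L)
  }
  structure(list(
    mol = mol,
    atom_count = M,
    atom_features = feats$atom_features,
    bond_features = bf,
    conformers = conformers,
    holo_coords = holo_coords,
    affinity = affinity
  ), class = "ligand_record")
}

#' Construct a pocket record
#'
#' Rigid binding-pocket heavy atoms with fixed crystal coordinates.
#'
#' @param elements Character vector of element symbols (no hydrogens).
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param residue_ids Per-atom residue label (any atomic vector).
#' @param is_backbone Optional logical vector (protein backbone flag); used
#'   as one feature bit, defaults to all `FALSE`.
#' @return Object of class `pocket_record` with `atom_count`, `elements`,
#'   `atom_features` (N x 12), `coords`, `residue_ids`.
#' @export
pocket_record <- function(elements, coords, residue_ids = seq_along(elements),
                          is_backbone = NULL) {
  N <- length(elements)
  if (N < 4L) stop("pocket must have at least 4 atoms to pin a pose")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == N, ncol(coords) == 3L)
  if (!all(is.finite(coords))) stop("pocket coordinates must be finite")
  if (any(elements %in% c("H", "D"))) stop("hydrogens must be stripped")
  if (is.null(is_backbone)) is_backbone <- rep(FALSE, N)
  structure(list(
    atom_count = N,
    elements = elements,
    atom_features = featurize_pocket_atoms(elements, is_backbone),
    coords = coords,
    residue_ids = residue_ids
  ), class = "pocket_record")
}

#' @export
print.ligand_record <- function(x, ...) {
  cat(sprintf("<ligand_record> %d heavy atoms, %d bonds, %d conformer(s)%s%s\n",
              x$atom_count, nrow(x$mol$bonds), length(x$conformers),
              if (!is.null(x$holo_coords)) ", holo pose" else "",
              if (!is.null(x$affinity)) sprintf(", pK = %.2f", x$affinity) else ""))
  invisible(x)
}

#' @export
print.pocket_record <- function(x, ...) {
  cat(sprintf("<pocket_record> %d heavy atoms in %d residues\n",
              x$atom_count, length(unique(x$residue_ids))))
  invisible(x)
}

#' Minimal internal molecule structure
#'
#' The light-weight bond-graph representation consumed by [featurize()] and
#' the conformer generator. Parsed files and the synthetic generator both
#' produce this form.
#'
#' @param elements Character vector of element symbols (heavy atoms only).
#' @param bonds Data frame with integer columns `i`, `k` (1-based atom
#'   indices, i < k), `order` (1, 2, 3) and logical `aromatic`.
#' @param charges Integer formal charges (default all 0).
#' @param name Molecule name.
#' @return Object of class `pd_mol`; ring membership and hybridization are
#'   derived from the graph.
#' @export
pd_mol <- function(elements, bonds, charges = NULL, name = "mol") {
  M <- length(elements)
  if (is.null(charges)) charges <- integer(M)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    stopifnot(all(bonds$i >= 1), all(bonds$k <= M), all(bonds$i != bonds$k))
    swap <- bonds$i > bonds$k
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$k[swap]; bonds$k[swap] <- tmp
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
  } else {
    bonds <- data.frame(i = integer(), k = integer(), order = integer(),
                        aromatic = logical())
  }
  m <- structure(list(elements = elements, bonds = bonds,
                      charges = as.integer(charges), name = name),
                 class = "pd_mol")
  m$bonds$in_ring <- bond_in_ring(m)
  m$atom_in_ring <- atom_in_ring(m)
  m$hybridization <- infer_hybridization(m)
  m$bonds$conjugated <- infer_conjugation(m)
  m
}

# A bond is in a ring iff its endpoints stay connected after removing it.
bond_in_ring <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  M <- length(mol$elements)
  out <- logical(nb)
  for (b in seq_len(nb)) {
    adj <- vector("list", M)
    for (b2 in seq_len(nb)) {
      if (b2 == b) next
      i <- mol$bonds$i[b2]; k <- mol$bonds$k[b2]
      adj[[i]] <- c(adj[[i]], k); adj[[k]] <- c(adj[[k]], i)
    }
    # BFS from i looking for k
    src <- mol$bonds$i[b]; dst <- mol$bonds$k[b]
    seen <- logical(M); seen[src] <- TRUE; queue <- src
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (nx in adj[[cur]]) if (!seen[nx]) { seen[nx] <- TRUE; queue <- c(queue, nx) }
    }
    out[b] <- seen[dst]
  }
  out
}

atom_in_ring <- function(mol) {
  out <- logical(length(mol$elements))
  rb <- mol$bonds[mol$bonds$in_ring, , drop = FALSE]
  out[c(rb$i, rb$k)] <- TRUE
  out
}

# sp if a triple bond or two double bonds touch the atom; sp2 if any double
# or aromatic bond does; sp3 for ordinary organic elements; "other" otherwise.
infer_hybridization <- function(mol) {
  M <- length(mol$elements)
  n_triple <- integer(M); n_double <- integer(M); n_arom <- integer(M)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; k <- mol$bonds$k[b]
    if (mol$bonds$aromatic[b]) {
      n_arom[i] <- n_arom[i] + 1L; n_arom[k] <- n_arom[k] + 1L
    } else if (mol$bonds$order[b] == 3L) {
      n_triple[i] <- n_triple[i] + 1L; n_triple[k] <- n_triple[k] + 1L
    } else if (mol$bonds$order[b] == 2L) {
      n_double[i] <- n_double[i] + 1L; n_double[k] <- n_double[k] + 1L
    }
  }
  organic <- mol$elements %in% c("C", "N", "O", "S", "P", "B")
  ifelse(n_triple > 0L | n_double >= 2L, "sp",
         ifelse(n_double > 0L | n_arom > 0L, "sp2",
                ifelse(organic, "sp3", "other")))
}

# A bond is conjugated when both endpoints are sp/sp2 centres.
infer_conjugation <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  hy <- mol$hybridization
  (hy[mol$bonds$i] %in% c("sp", "sp2")) & (hy[mol$bonds$k] %in% c("sp", "sp2"))
}
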