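# One-hot featurization over heavy atoms.
#
# Fixed vocabulary (all blocks one-hot, out-of-vocabulary -> "other"):
#   atoms: element {C,N,O,S,P,F,Cl,Br,I,B,other} (11)
#          + degree 0..5 clamped (6) + formal charge -2..+2 clamped (5)
#          + aromatic (1) + in-ring (1) + hybridization {sp,sp2,sp3,other} (4)
#          = 28 columns
#   bonds: type {single,double,triple,aromatic} (4) + conjugated (1)
#          + in-ring (1) = 6 columns; unbonded pairs get an all-zero row
#   pocket atoms: element (11) + backbone bit (1) = 12 columns

PD_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "other")

#' Feature dimensions of the fixed vocabulary
#' @return Named list with `ligand_atom`, `pocket_atom`, `bond` and
#'   `n_pair_types` entries.
#' @export
pd_feature_dims <- function() {
  ne <- length(PD_ELEMENTS)
  list(ligand_atom = ne + 6L + 5L + 1L + 1L + 4L,
       pocket_atom = ne + 1L,
       bond = 6L,
       n_pair_types = ne * (ne + 1L) %/% 2L)
}

element_bucket <- function(el) {
  i <- match(el, PD_ELEMENTS)
  i[is.na(i)] <- length(PD_ELEMENTS)
  i
}

#' Unordered pair-type index of two element symbols
#'
#' Pair types feed the pair-type aware affine transform of the Gaussian
#' distance encoding; the type of (i, k) equals the type of (k, i).
#' @param el_i,el_k Element symbols (vectors recycle).
#' @return Integer in `1..n_pair_types`.
#' @export
pd_pair_type <- function(el_i, el_k) {
  a <- element_bucket(el_i); b <- element_bucket(el_k)
  lo <- pmin(a, b); hi <- pmax(a, b)
  ne <- length(PD_ELEMENTS)
  # index of unordered pair (lo, hi), lo <= hi, row-wise over the triangle
  (lo - 1L) * ne - (lo - 1L) * lo %/% 2L + hi - lo + 1L
}

one_hot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' One-hot featurization of a molecule
#'
#' Coordinate-free: identical output for every conformer of the molecule.
#'
#' @param mol A [pd_mol()] object (heavy atoms only).
#' @return List with `atom_features` (M x 28 matrix) and `bond_features`
#'   ((M*M) x 6 matrix, flattened row-major, symmetric, zero when unbonded).
#' @export
featurize <- function(mol) {
  M <- length(mol$elements)
  deg <- integer(M)
  for (b in seq_len(nrow(mol$bonds))) {
    deg[mol$bonds$i[b]] <- deg[mol$bonds$i[b]] + 1L
    deg[mol$bonds$k[b]] <- deg[mol$bonds$k[b]] + 1L
  }
  hyb <- match(mol$hybridization, c("sp", "sp2", "sp3"))
  hyb[is.na(hyb)] <- 4L
  atom <- cbind(
    one_hot(element_bucket(mol$elements), length(PD_ELEMENTS)),
    one_hot(pmin(deg, 5L) + 1L, 6L),
    one_hot(pmax(pmin(mol$charges, 2L), -2L) + 3L, 5L),
    as.numeric(atom_aromatic(mol)),
    as.numeric(mol$atom_in_ring),
    one_hot(hyb, 4L)
  )
  bond <- matrix(0, M * M, 6L)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; k <- mol$bonds$k[b]
    type <- if (mol$bonds$aromatic[b]) 4L else mol$bonds$order[b]
    row <- c(one_hot(type, 4L), as.numeric(mol$bonds$conjugated[b]),
             as.numeric(mol$bonds$in_ring[b]))
    bond[pair_row(i, k, M), ] <- row
    bond[pair_row(k, i, M), ] <- row
  }
  list(atom_features = atom, bond_features = bond)
}

atom_aromatic <- function(mol) {
  out <- logical(length(mol$elements))
  ab <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
  out[c(ab$i, ab$k)] <- TRUE
  out
}

#' One-hot features for pocket atoms
#' @param elements Element symbols.
#' @param is_backbone Logical protein-backbone flag.
#' @return N x 12 matrix.
#' @export
featurize_pocket_atoms <- function(elements, is_backbone) {
  cbind(one_hot(element_bucket(elements), length(PD_ELEMENTS)),
        as.numeric(is_backbone))
}
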