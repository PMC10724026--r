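# Binding-pocket extraction: residue-level 6 Angstrom rule.
#
# A residue belongs to the pocket when ANY of its heavy atoms lies within
# `cutoff` of ANY ligand heavy atom; all heavy atoms of a selected residue
# are returned (whole residue in or out). Waters, ions and other hetero
# residues are excluded by default.

#' Read a protein structure into an atom table
#'
#' Thin wrapper over [bio3d::read.pdb()] producing the flat atom table
#' consumed by [extract_pocket()]. Hydrogens are dropped.
#'
#' @param path Path to a PDB file.
#' @return Data frame with columns `element`, `x`, `y`, `z`, `res_key`,
#'   `res_name`, `is_backbone`, `hetero`.
#' @export
read_protein <- function(path) {
  frame_from_pdb(bio3d::read.pdb(path))
}

frame_from_pdb <- function(pdb) {
  at <- pdb$atom
  element <- at$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- substr(trimws(at$elety[blank]), 1L, 1L)
  element <- sub("^([A-Za-z])([a-z]?).*$", "\\1\\2", element)
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  element <- sub(" $", "", element)
  df <- data.frame(
    element = trimws(element),
    x = at$x, y = at$y, z = at$z,
    res_key = paste(at$chain, at$resno, at$insert, sep = "_"),
    res_name = at$resid,
    is_backbone = at$elety %in% c("N", "CA", "C", "O", "OXT") &
      at$type == "ATOM",
    hetero = at$type == "HETATM" | at$resid %in% c("HOH", "WAT", "DOD"),
    stringsAsFactors = FALSE
  )
  df[!(df$element %in% c("H", "D")), , drop = FALSE]
}

#' Extract the binding pocket around a ligand pose
#'
#' Selects every residue containing at least one heavy atom within `cutoff`
#' (default 6 Angstrom) of any ligand heavy atom, and returns all heavy
#' atoms of the selected residues.
#'
#' @param protein A `bio3d` `pdb` object, a PDB file path, or an atom table
#'   as returned by [read_protein()].
#' @param ligand_coords M x 3 matrix of ligand heavy-atom coordinates.
#' @param cutoff Distance cutoff in Angstrom (default 6.0).
#' @param include_hetero Include waters/ions/cofactors (default `FALSE`).
#' @return A [pocket_record()].
#' @export
extract_pocket <- function(protein, ligand_coords, cutoff = 6.0,
                           include_hetero = FALSE) {
  frame <- protein_frame(protein)
  if (!include_hetero) frame <- frame[!frame$hetero, , drop = FALSE]
  if (!nrow(frame)) stop("protein has no usable residues")
  ligand_coords <- as.matrix(ligand_coords)
  stopifnot(ncol(ligand_coords) == 3L, all(is.finite(ligand_coords)))

  pc <- as.matrix(frame[, c("x", "y", "z")])
  d2 <- outer(rowSums(pc^2), rowSums(ligand_coords^2), "+") -
    2 * pc %*% t(ligand_coords)
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  hit_res <- unique(frame$res_key[mind <= cutoff])
  if (!length(hit_res)) stop("no pocket residues within cutoff")
  sel <- frame$res_key %in% hit_res
  pocket_record(
    elements = frame$element[sel],
    coords = pc[sel, , drop = FALSE],
    residue_ids = frame$res_key[sel],
    is_backbone = frame$is_backbone[sel]
  )
}

protein_frame <- function(protein) {
  if (is.data.frame(protein)) {
    needed <- c("element", "x", "y", "z", "res_key")
    stopifnot(all(needed %in% names(protein)))
    if (is.null(protein$hetero)) protein$hetero <- FALSE
    if (is.null(protein$is_backbone)) protein$is_backbone <- FALSE
    protein[!(protein$element %in% c("H", "D")), , drop = FALSE]
  } else if (inherits(protein, "pdb")) {
    frame_from_pdb(protein)
  } else if (is.character(protein) && length(protein) == 1L) {
    read_protein(protein)
  } else {
    stop("unsupported protein input")
  }
}
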