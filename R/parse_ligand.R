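# Ligand input: SDF / MOL2 files or SMILES strings, via ChemmineR (and
# ChemmineOB for format conversion). Hydrogens are stripped and atoms keep
# file order; unparsable molecules raise a classed parse error so callers
# can exclude them rather than crash.

#' Parse a ligand from SDF, MOL2 or SMILES
#'
#' @param x Path to an `.sdf`/`.mol`/`.mol2` file, or a SMILES string.
#' @return A [ligand_record()]; the file's coordinates (if any) are stored
#'   as the first conformer.
#' @export
parse_ligand <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  sdf <- tryCatch({
    if (file.exists(x) && grepl("\\.(sdf|mol)$", x, ignore.case = TRUE)) {
      ChemmineR::read.SDFset(x)
    } else if (file.exists(x) && grepl("\\.mol2$", x, ignore.case = TRUE)) {
      out <- tempfile(fileext = ".sdf")
      ChemmineOB::convertFormatFile("MOL2", "SDF", x, out)
      ChemmineR::read.SDFset(out)
    } else {
      ChemmineR::smiles2sdf(x)
    }
  }, error = function(e) {
    stop(ligand_parse_error(x, conditionMessage(e)))
  })
  ok <- length(sdf) >= 1L &&
    nrow(ChemmineR::atomblock(sdf[[1]])) >= 2L &&
    nrow(ChemmineR::bondblock(sdf[[1]])) >= 1L
  if (!ok) stop(ligand_parse_error(x, "no valid molecule found"))
  sdf_to_ligand(sdf[[1]], name = if (file.exists(x)) basename(x) else x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ligand_parse_error <- function(input, msg) {
  structure(class = c("pd_parse_error", "error", "condition"),
            list(message = sprintf("could not parse ligand '%s': %s", input, msg),
                 call = NULL))
}

# Convert one ChemmineR::SDF to a ligand_record, dropping hydrogens.
sdf_to_ligand <- function(sdf, name = "mol") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:3, drop = FALSE]
  # MDL charge codes: 1..3 -> +3..+1, 5..7 -> -1..-3 (col "C6" of the block)
  chcol <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charges <- integer(length(chcol))
  charges[chcol >= 1 & chcol <= 3] <- 4L - as.integer(chcol[chcol >= 1 & chcol <= 3])
  charges[chcol >= 5 & chcol <= 7] <- 4L - as.integer(chcol[chcol >= 5 & chcol <= 7])

  heavy <- !(elements %in% c("H", "D"))
  if (sum(heavy) < 2L) stop(ligand_parse_error(name, "fewer than 2 heavy atoms"))
  newidx <- cumsum(heavy)

  bonds <- data.frame(i = as.integer(bb[, 1]), k = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  keep <- heavy[bonds$i] & heavy[bonds$k]
  bonds <- bonds[keep, , drop = FALSE]
  bonds$aromatic <- bonds$order == 4L
  bonds$order[bonds$aromatic] <- 1L
  bonds$i <- newidx[bonds$i]; bonds$k <- newidx[bonds$k]

  # aromaticity of kekulized rings via ChemmineR ring perception
  arom_atoms <- tryCatch({
    r <- ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = TRUE)
    if (length(r$AROMATIC) && any(r$AROMATIC)) {
      unique(unlist(lapply(r$RINGS[r$AROMATIC], function(ring) {
        as.integer(sub("^.*_", "", ring))
      })))
    } else integer(0)
  }, error = function(e) integer(0))
  if (length(arom_atoms)) {
    arom_atoms <- newidx[intersect(arom_atoms, which(heavy))]
    in_arom <- bonds$i %in% arom_atoms & bonds$k %in% arom_atoms
    bonds$aromatic <- bonds$aromatic | in_arom
    bonds$order[bonds$aromatic] <- 1L
  }

  mol <- pd_mol(elements[heavy], bonds, charges[heavy], name = name)
  cf <- unname(as.matrix(coords[heavy, , drop = FALSE]))
  conformers <- if (any(abs(cf) > 0)) list(cf) else list()
  ligand_record(mol, conformers = conformers)
}
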