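# Preprocessed-complex JSON-lines format, pose/SDF output, checkpoints.

ligand_to_list <- function(lig) {
  list(elements = lig$mol$elements,
       charges = lig$mol$charges,
       name = lig$mol$name,
       bonds = lig$mol$bonds[, c("i", "k", "order", "aromatic")],
       conformers = lapply(lig$conformers, identity),
       holo_coords = lig$holo_coords,
       affinity = lig$affinity)
}

as_coord_matrix <- function(x) {
  m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, unlist))
  storage.mode(m) <- "double"
  unname(m)
}

#' Write preprocessed complexes as JSON lines
#'
#' One record per complex (ligand graph + conformers + optional holo pose
#' and label, pocket atoms + coordinates); the format training consumes.
#' @param complexes List of `list(ligand, pocket)`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_complexes_jsonl <- function(complexes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cx in complexes) {
    rec <- list(ligand = ligand_to_list(cx$ligand),
                pocket = list(elements = cx$pocket$elements,
                              coords = cx$pocket$coords,
                              residue_ids = cx$pocket$residue_ids))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read complexes from JSON lines
#' @param path File written by [write_complexes_jsonl()].
#' @return List of `list(ligand, pocket)`.
#' @export
read_complexes_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line, simplifyMatrix = TRUE)
    lig <- rec$ligand
    mol <- pd_mol(lig$elements, as.data.frame(lig$bonds), lig$charges,
                  name = lig$name %||% "mol")
    conformers <- lig$conformers
    if (is.array(conformers) && length(dim(conformers)) == 3L) {
      # jsonlite collapses equally-sized conformers into one 3-d array
      conformers <- lapply(seq_len(dim(conformers)[1]),
                           function(i) conformers[i, , ])
    } else if (is.matrix(conformers)) {
      conformers <- list(conformers)
    }
    list(
      ligand = ligand_record(
        mol,
        conformers = lapply(conformers, as_coord_matrix),
        holo_coords = if (is.null(lig$holo_coords)) NULL else
          as_coord_matrix(lig$holo_coords),
        affinity = lig$affinity),
      pocket = pocket_record(rec$pocket$elements,
                             as_coord_matrix(rec$pocket$coords),
                             rec$pocket$residue_ids)
    )
  })
}

#' Write a ligand pose as an SDF file
#'
#' Single-conformer V2000 record in the original atom order.
#' @param ligand A [ligand_record()] (bond graph source).
#' @param coords M x 3 coordinates to write.
#' @param path Output file.
#' @param name Molecule name for the header.
#' @return `path`, invisibly.
#' @export
write_pose_sdf <- function(ligand, coords, path, name = ligand$mol$name) {
  mol <- ligand$mol
  M <- length(mol$elements)
  nb <- nrow(mol$bonds)
  lines <- c(
    name, "  pairdock", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", M, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], mol$elements),
    if (nb) sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i, mol$bonds$k,
                    ifelse(mol$bonds$aromatic, 4L, mol$bonds$order)),
    if (any(mol$charges != 0)) {
      ch <- which(mol$charges != 0)
      sprintf("M  CHG%3d%s", length(ch),
              paste(sprintf("%4d%4d", ch, mol$charges[ch]), collapse = ""))
    },
    "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}

#' Save model parameters and configuration
#' @param model A [pd_model()].
#' @param path Destination (RDS).
#' @return `path`, invisibly.
#' @export
pd_save_checkpoint <- function(model, path) {
  leaves <- ad_collect_params(model$params)
  saveRDS(list(cfg = unclass(model$cfg),
               values = lapply(leaves, function(p) p$value)), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path File written by [pd_save_checkpoint()].
#' @return A [pd_model()] with restored weights.
#' @export
pd_load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(pd_config, ck$cfg[names(formals(pd_config))])
  model <- pd_model(cfg, seed = 1L)
  leaves <- ad_collect_params(model$params)
  stopifnot(length(leaves) == length(ck$values))
  for (i in seq_along(leaves)) leaves[[i]]$value <- ck$values[[i]]
  model
}
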