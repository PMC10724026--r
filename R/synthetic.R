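# Synthetic pocket-ligand complexes.
#
# Fully seeded toy complexes exercising every pipeline stage without
# external data: a random branched/ringed small molecule with a planted
# bound (holo) pose, a rigid non-coplanar pocket shell around that pose, a
# pK label that is a smooth noisy function of the planted contact count,
# and apo conformers re-embedded independently of the holo pose.

#' Generate a synthetic pocket-ligand complex
#'
#' @param M Ligand heavy atoms (>= 3).
#' @param N Pocket heavy atoms (>= 6).
#' @param flexibility S.d. (Angstrom) of the per-atom jitter applied to apo
#'   conformers on top of independent re-embedding (default 0.3).
#' @param n_conformers Apo conformers to attach (default 10, matching the
#'   representative-conformer protocol).
#' @param seed Integer seed; the complex is fully determined by it.
#' @return List with `ligand` (a [ligand_record()] with holo pose, apo
#'   conformers and pK label), `pocket` (a [pocket_record()]) and `pk`.
#' @export
make_synthetic_complex <- function(M = 10L, N = 16L, flexibility = 0.3,
                                   n_conformers = 10L, seed = 1L) {
  stopifnot(M >= 3L, N >= 6L)
  set.seed(seed)
  mol <- random_molecule(M)
  holo <- dg_embed(mol, seed = seed + 13L)

  # pocket shell: points 2.5-5 A from a random ligand atom, clash-rejected
  pocket_xyz <- matrix(0, N, 3L)
  got <- 0L
  while (got < N) {
    anchor <- holo[sample.int(M, 1L), ]
    u <- rnorm(3L); u <- u / sqrt(sum(u^2))
    p <- anchor + stats::runif(1L, 2.5, 5.0) * u
    if (min(sqrt(rowSums((holo - rep(p, each = M))^2))) < 2.2) next
    got <- got + 1L
    pocket_xyz[got, ] <- p
  }
  pocket <- pocket_record(
    elements = sample(c("C", "N", "O", "S"), N, replace = TRUE,
                      prob = c(0.6, 0.2, 0.15, 0.05)),
    coords = pocket_xyz,
    residue_ids = ceiling(seq_len(N) / 4)
  )

  contacts <- sum(cross_dist(holo, pocket_xyz) < 4)
  pk <- 2 + 8 * contacts / (contacts + 30) + stats::rnorm(1L, sd = 0.2)

  conformers <- lapply(seq_len(n_conformers), function(i) {
    x <- dg_embed(mol, seed = seed + 1000L * i)
    x + matrix(stats::rnorm(M * 3L, sd = flexibility), M, 3L)
  })
  lig <- ligand_record(mol, conformers = conformers, holo_coords = holo,
                       affinity = pk)
  list(ligand = lig, pocket = pocket, pk = pk)
}

# Random connected molecule: chain growth with branching, valence caps,
# occasional double bonds and one optional ring closure.
random_molecule <- function(M) {
  max_val <- c(C = 4L, N = 3L, O = 2L)
  elements <- sample(c("C", "N", "O"), M, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
  used <- integer(M)
  bi <- integer(0); bk <- integer(0); bo <- integer(0)
  for (a in 2L:M) {
    cand <- which(used[seq_len(a - 1L)] < max_val[elements[seq_len(a - 1L)]])
    if (!length(cand)) cand <- a - 1L
    parent <- if (length(cand) == 1L) cand else {
      # bias towards recent atoms for chain-like topology
      sample(cand, 1L, prob = seq_along(cand)^2)
    }
    order <- 1L
    if (stats::runif(1L) < 0.15 &&
        used[parent] + 2L <= max_val[elements[parent]] &&
        max_val[elements[a]] >= 2L) {
      order <- 2L
    }
    bi <- c(bi, parent); bk <- c(bk, a); bo <- c(bo, order)
    used[parent] <- used[parent] + order
    used[a] <- used[a] + order
  }
  if (M >= 5L && stats::runif(1L) < 0.4) {
    free <- which(used < max_val[elements])
    if (length(free) >= 2L) {
      pair <- sample(free, 2L)
      already <- any((bi == min(pair) & bk == max(pair)))
      if (!already && abs(pair[1L] - pair[2L]) >= 3L) {
        bi <- c(bi, pair[1L]); bk <- c(bk, pair[2L]); bo <- c(bo, 1L)
      }
    }
  }
  pd_mol(elements, data.frame(i = bi, k = bk, order = bo, aromatic = FALSE),
         name = "synthetic")
}
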