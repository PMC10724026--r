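# Unbound (apo) conformer generation.
#
# Conformers are embedded by distance geometry: bond lengths and 1-3
# distances derived from the bond graph (covalent radii, ideal angles by
# hybridization) define a stress function that is minimized by L-BFGS from
# seeded random starts; torsional diversity comes from the random
# initialization. The pool is then reduced to a small representative set by
# KMeans clustering on flattened pairwise heavy-atom distance matrices (a
# rotation/translation-invariant feature), keeping the member closest to
# each cluster centre.

PD_COV_RADII <- c(C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06, F = 0.71,
                  Cl = 0.99, Br = 1.14, I = 1.33, B = 0.82, other = 0.77)

ideal_bond_length <- function(el_i, el_k, order, aromatic) {
  r <- PD_COV_RADII[element_bucket(el_i)] + PD_COV_RADII[element_bucket(el_k)]
  f <- ifelse(aromatic, 0.93, c(1, 0.87, 0.78)[pmin(order, 3L)])
  unname(r * f)
}

# Distance constraints from the bond graph: exact bonds, 1-3 distances via
# ideal angles at the central atom, and a 2.4 A lower bound elsewhere.
dg_constraints <- function(mol) {
  M <- length(mol$elements)
  b <- mol$bonds
  blen <- ideal_bond_length(mol$elements[b$i], mol$elements[b$k],
                            b$order, b$aromatic)
  bl <- matrix(NA_real_, M, M)
  bl[cbind(b$i, b$k)] <- blen
  bl[cbind(b$k, b$i)] <- blen

  ang <- c(sp = pi, sp2 = 2 * pi / 3, sp3 = 109.47 * pi / 180,
           other = 109.47 * pi / 180)
  i13 <- integer(0); k13 <- integer(0); d13 <- numeric(0)
  for (j in seq_len(M)) {
    nb <- sort(unique(c(b$k[b$i == j], b$i[b$k == j])))
    if (length(nb) < 2L) next
    th <- ang[[mol$hybridization[j]]]
    for (u in seq_along(nb)) for (v in seq_len(u - 1L)) {
      a1 <- nb[u]; a2 <- nb[v]
      if (!is.na(bl[a1, a2])) next  # already bonded (3-ring)
      d1 <- bl[j, a1]; d2 <- bl[j, a2]
      i13 <- c(i13, a1); k13 <- c(k13, a2)
      d13 <- c(d13, sqrt(d1^2 + d2^2 - 2 * d1 * d2 * cos(th)))
    }
  }
  exact <- rbind(
    data.frame(i = b$i, k = b$k, d = blen, w = 10),
    data.frame(i = i13, k = k13, d = d13, w = 5)
  )
  exact <- exact[!duplicated(paste(pmin(exact$i, exact$k),
                                   pmax(exact$i, exact$k))), , drop = FALSE]
  seen <- matrix(FALSE, M, M)
  seen[cbind(exact$i, exact$k)] <- TRUE
  seen[cbind(exact$k, exact$i)] <- TRUE
  rep_pairs <- which(upper.tri(seen) & !seen, arr.ind = TRUE)
  list(exact = exact, repulse = rep_pairs, M = M)
}

dg_stress <- function(xvec, cons) {
  x <- matrix(xvec, cons$M, 3L)
  e <- cons$exact
  dv <- x[e$i, , drop = FALSE] - x[e$k, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  s <- sum(e$w * (d - e$d)^2)
  if (nrow(cons$repulse)) {
    rv <- x[cons$repulse[, 1], , drop = FALSE] - x[cons$repulse[, 2], , drop = FALSE]
    rd <- sqrt(rowSums(rv^2))
    s <- s + sum(pmax(0, 2.4 - rd)^2)
  }
  s
}

dg_stress_grad <- function(xvec, cons) {
  x <- matrix(xvec, cons$M, 3L)
  g <- matrix(0, cons$M, 3L)
  e <- cons$exact
  dv <- x[e$i, , drop = FALSE] - x[e$k, , drop = FALSE]
  d <- pmax(sqrt(rowSums(dv^2)), 1e-9)
  coef <- 2 * e$w * (d - e$d) / d
  gi <- coef * dv
  g <- g + rowsum_into(gi, e$i, cons$M) - rowsum_into(gi, e$k, cons$M)
  if (nrow(cons$repulse)) {
    ri <- cons$repulse[, 1]; rk <- cons$repulse[, 2]
    rv <- x[ri, , drop = FALSE] - x[rk, , drop = FALSE]
    rd <- pmax(sqrt(rowSums(rv^2)), 1e-9)
    pen <- pmax(0, 2.4 - rd)
    coef <- -2 * pen / rd
    gr <- coef * rv
    g <- g + rowsum_into(gr, ri, cons$M) - rowsum_into(gr, rk, cons$M)
  }
  as.vector(g)
}

rowsum_into <- function(mat, idx, n) {
  out <- matrix(0, n, ncol(mat))
  agg <- rowsum(mat, group = idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Embed one 3D conformer by distance geometry
#'
#' @param mol A [pd_mol()].
#' @param seed Integer seed controlling the random start.
#' @param max_retry Retries with fresh starts before giving up.
#' @return M x 3 coordinate matrix.
#' @export
dg_embed <- function(mol, seed = 1L, max_retry = 5L) {
  cons <- dg_constraints(mol)
  M <- cons$M
  for (attempt in seq_len(max_retry)) {
    set.seed(seed + 7919L * (attempt - 1L))
    x0 <- rnorm(M * 3L, sd = max(1.5, 0.4 * M^(2 / 3)))
    opt <- stats::optim(x0, dg_stress, dg_stress_grad, cons = cons,
                        method = "L-BFGS-B",
                        control = list(maxit = 500L, factr = 1e4))
    x <- matrix(opt$par, M, 3L)
    e <- cons$exact
    bond_rows <- e$w == 10
    dv <- x[e$i[bond_rows], , drop = FALSE] - x[e$k[bond_rows], , drop = FALSE]
    dev <- abs(sqrt(rowSums(dv^2)) - e$d[bond_rows])
    if (!length(dev) || max(dev) < 0.3) return(x)
  }
  stop(sprintf("distance-geometry embedding failed for molecule '%s' after %d attempts",
               mol$name, max_retry))
}

#' Generate clustered unbound conformers
#'
#' Embeds `n_generate` conformers with seeded random starts, clusters their
#' flattened pairwise-distance matrices with KMeans into `n_keep` groups and
#' stores one representative per cluster (the member nearest the cluster
#' centre) in the record's `conformers`.
#'
#' @param ligand A [ligand_record()].
#' @param n_generate Conformers to embed (default 100).
#' @param n_keep Representatives to retain (default 10).
#' @param seed Integer seed; fixes both embedding and clustering.
#' @return The ligand record with `conformers` replaced.
#' @export
generate_conformers <- function(ligand, n_generate = 100L, n_keep = 10L,
                                seed = 1L) {
  stopifnot(inherits(ligand, "ligand_record"))
  pool <- lapply(seq_len(n_generate), function(i) {
    dg_embed(ligand$mol, seed = seed + 104729L * i)
  })
  if (n_keep >= n_generate) {
    ligand$conformers <- pool
    return(ligand)
  }
  feats <- t(vapply(pool, function(x) as.vector(as.matrix(stats::dist(x))),
                    numeric(ligand$atom_count^2)))
  n_distinct <- nrow(unique(round(feats, 6)))
  set.seed(seed)
  if (n_distinct <= n_keep) {
    # (near-)rigid molecule: clustering is degenerate, keep n_keep members
    reps <- pool[rep_len(seq_len(n_generate), n_keep)]
  } else {
    km <- stats::kmeans(feats, centers = n_keep, nstart = 5L, iter.max = 100L)
    reps <- lapply(seq_len(n_keep), function(cl) {
      members <- which(km$cluster == cl)
      dists <- colSums((t(feats[members, , drop = FALSE]) - km$centers[cl, ])^2)
      pool[[members[which.min(dists)]]]
    })
  }
  ligand$conformers <- reps
  ligand
}
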