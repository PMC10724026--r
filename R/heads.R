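# Prediction block (distance + affinity heads) and the three-part
# smooth-L1 training objective.

#' Predict distance maps from the final pair tensors
#'
#' Per-pair linear projection to a scalar; the intra-ligand map is
#' symmetrized as (D(t_ik) + D(t_ki)) / 2. Units are Angstrom.
#'
#' @param pars Head parameters.
#' @param t Ligand pair node ((M*M) x d_pair).
#' @param z Complex pair node ((M*N) x d_pair).
#' @param M,N Atom counts.
#' @return List of nodes `D_lig` ((M*M) x 1, symmetrized) and `D_inter`
#'   ((M*N) x 1), flattened row-major.
#' @export
predict_distances <- function(pars, t, z, M, N) {
  d_lig_raw <- apply_lin(apply_ln(t, pars$ln_t), pars$d_lig)
  perm <- chan_tperm(M, M)
  d_lig <- ad_scale(ad_add(d_lig_raw, ad_permute_rows(d_lig_raw, perm)), 0.5)
  d_inter <- apply_lin(apply_ln(z, pars$ln_z), pars$d_inter)
  list(D_lig = d_lig, D_inter = d_inter)
}

#' Predict the binding affinity
#'
#' Per complex pair, `concat(z_ij, m_i, n_j)` passes through a gated linear
#' unit, is mean-pooled over all M*N pairs, and a final linear head maps the
#' pooled vector to the scalar pK prediction.
#'
#' @param pars Head parameters.
#' @param z Complex pair node.
#' @param m,n Atom embedding nodes.
#' @param M,N Atom counts.
#' @return Scalar node (1 x 1).
#' @export
predict_affinity <- function(pars, z, m, n, M, N) {
  zn <- apply_ln(z, pars$ln_z)
  mi <- ad_gather_rows(apply_ln(m, pars$ln_m), rep(seq_len(M), each = N))
  nj <- ad_gather_rows(apply_ln(n, pars$ln_n), rep(seq_len(N), times = M))
  a_ij <- apply_glu(ad_concat_cols(list(zn, mi, nj)), pars$aff_glu)
  apply_lin(ad_colmeans(a_ij), pars$aff_out)
}

prediction_heads <- function(pars, cfg, z, t, m, n, M, N) {
  d <- predict_distances(pars, t, z, M, N)
  aff <- predict_affinity(pars, z, m, n, M, N)
  list(D_lig = d$D_lig, D_inter = d$D_inter, affinity = aff)
}

#' Smooth-L1 (Huber) penalty
#'
#' `0.5 (x-y)^2` when `|x-y| < 1`, else `|x-y| - 0.5`; continuous and once
#' differentiable at the branch point (both branches give 0.5).
#' @param x,y Numeric scalars/arrays of equal shape.
#' @return Elementwise penalty, same shape.
#' @export
smooth_l1 <- function(x, y) {
  r <- x - y
  a <- abs(r)
  ifelse(a < 1, 0.5 * r * r, a - 0.5)
}

#' Ground-truth distance maps from a holo pose
#'
#' @param holo M x 3 holo ligand coordinates.
#' @param pocket_coords N x 3 pocket coordinates.
#' @return List `D_lig` (M x M), `D_inter` (M x N), in Angstrom.
#' @export
true_distance_maps <- function(holo, pocket_coords) {
  list(D_lig = as.matrix(stats::dist(holo)),
       D_inter = cross_dist(holo, pocket_coords))
}

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Training loss for one complex
#'
#' Mean smooth-L1 over the full intermolecular (M*N) and intra-ligand (M*M,
#' diagonal included) distance maps plus smooth-L1 on the affinity,
#' weighted by `alpha`, `beta`, `gamma`.
#'
#' @param pred_nodes List with nodes `D_inter`, `D_lig`, `affinity` (as
#'   produced by the prediction heads).
#' @param truth List with `D_inter` (M x N), `D_lig` (M x M) and optional
#'   scalar `affinity` (pK).
#' @param cfg A `pd_config` (weights and `auto_zero_gamma`).
#' @return Scalar loss node.
#' @export
total_loss <- function(pred_nodes, truth, cfg) {
  gamma <- cfg$gamma
  if (is.null(truth$affinity) || is.na(truth$affinity %||% NA)) {
    if (gamma > 0 && !cfg$auto_zero_gamma) {
      stop("affinity label missing with gamma > 0")
    }
    gamma <- 0
  }
  l <- ad_scale(ad_smooth_l1_mean(pred_nodes$D_inter,
                                  as.vector(t(truth$D_inter))), cfg$alpha)
  l <- ad_add(l, ad_scale(ad_smooth_l1_mean(pred_nodes$D_lig,
                                            as.vector(t(truth$D_lig))),
                          cfg$beta))
  if (gamma > 0) {
    l <- ad_add(l, ad_scale(ad_smooth_l1_mean(pred_nodes$affinity,
                                              truth$affinity), gamma))
  }
  l
}
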