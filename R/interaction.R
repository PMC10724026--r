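# Mutual interaction block.
#
# The complex pair tensor z (ligand x pocket) is initialized from the outer
# product of the two atom-embedding tracks and then co-evolves with the
# ligand pair tensor t over n_iter iterations of
#   complex triangular update -> complex axial attention ->
#   complex-to-ligand communication (+ one pair attention layer on t).
# The pocket pair tensor p is read-only here.

#' Initialize the complex pair tensor
#'
#' Outer product of ligand and pocket atom embeddings, flattened and
#' projected to `d_pair`.
#' @param m Ligand atom node (M x d_atom).
#' @param n Pocket atom node (N x d_atom).
#' @param W_z Projection parameters (`d_atom^2 -> d_pair`).
#' @return `adnode`, (M*N) x d_pair.
#' @export
init_complex_pair <- function(m, n, W_z) {
  apply_lin(ad_outer_rows(m, n), W_z)
}

#' Complex triangular update
#'
#' Pair (i,j) aggregates ligand-pair/complex-pair products through every
#' ligand atom k and complex-pair/pocket-pair products through every pocket
#' atom k'; gated residual output.
#'
#' @param state List with nodes `z`, `t`, `p` and sizes `M`, `N`.
#' @param pars Layer parameters.
#' @return Updated complex pair node.
#' @export
complex_triangular_update <- function(state, pars) {
  M <- state$M; N <- state$N
  zn <- apply_ln(state$z, pars$ln_z)
  tn <- apply_ln(state$t, pars$ln_t)
  pn <- apply_ln(state$p, pars$ln_p)
  a <- apply_glu(zn, pars$a)        # a_kj, lives on the complex grid
  b <- apply_glu(zn, pars$b)        # b_ik'
  tg <- apply_glu(tn, pars$tg)      # gated ligand pairs t_ik
  pg <- apply_glu(pn, pars$pg)      # gated pocket pairs p_k'j
  s <- ad_add(
    ad_chan_matmul(tg, a, M, M, M, N),   # sum_k t_ik a_kj
    ad_chan_matmul(b, pg, M, N, N, N)    # sum_k' b_ik' p_k'j
  )
  g <- ad_sigmoid(apply_lin(zn, pars$g))
  ad_add(state$z, ad_mul(g, apply_lin(s, pars$out)))
}

# Permutation that regroups a flattened M x N grid from i-major to j-major.
grid_transpose_perm <- function(M, N) chan_tperm(M, N)

caxial_branch <- function(z, pars, nblocks, H) {
  # standard gated MHA within contiguous row blocks of the (already
  # permuted, if needed) complex grid
  zn <- apply_ln(z, pars$ln)
  q <- apply_lin(zn, pars$q); k <- apply_lin(zn, pars$k)
  v <- apply_lin(zn, pars$v)
  att <- ad_block_mha(q, k, v, nblocks, H)
  g <- ad_sigmoid(apply_lin(zn, pars$gate))
  apply_lin(ad_mul(g, att), pars$o)
}

#' Complex axial attention
#'
#' Gated multi-head attention applied twice on the rectangular complex
#' grid: along rows (fixed ligand atom, attending over pocket atoms) and
#' along columns (fixed pocket atom, attending over ligand atoms), each
#' with a residual add. No third-edge bias: triangles do not close on the
#' rectangular grid.
#'
#' @inheritParams complex_triangular_update
#' @param cfg A `pd_config`.
#' @return Updated complex pair node.
#' @export
complex_axial_attention <- function(state, pars, cfg) {
  M <- state$M; N <- state$N
  z <- state$z
  z <- ad_add(z, caxial_branch(z, pars$crow, nblocks = M, H = cfg$n_heads))
  perm <- grid_transpose_perm(M, N)
  ip <- integer(length(perm)); ip[perm] <- seq_along(perm)
  zp <- ad_permute_rows(z, perm)
  upd <- caxial_branch(zp, pars$ccol, nblocks = N, H = cfg$n_heads)
  ad_add(z, ad_permute_rows(upd, ip))
}

#' Complex-to-ligand communication
#'
#' Ligand pair (i,k) receives the pooled product of its two atoms' complex
#' rows, `sum_j z_ij * z_kj`, through a gated residual update; a pair
#' attention layer (with this block's own weights) then restores geometric
#' consistency of the ligand pair tensor.
#'
#' @inheritParams complex_axial_attention
#' @return Updated ligand pair node.
#' @export
complex_to_ligand_communication <- function(state, pars, cfg) {
  M <- state$M; N <- state$N
  zn <- apply_ln(state$z, pars$comm$ln_z)
  tn <- apply_ln(state$t, pars$comm$ln_t)
  s <- ad_chan_matmul(zn, zn, M, N, M, N, tb = TRUE)  # sum_j z_ij z_kj
  g <- ad_sigmoid(apply_lin(tn, pars$comm$g))
  t1 <- ad_add(state$t, ad_mul(g, apply_lin(s, pars$comm$out)))
  if (cfg$use_self_triangular) {
    t1 <- self_triangular_update(t1, pars$pair_tri, M)
  }
  if (cfg$use_pair_axial) {
    t1 <- pair_axial_attention(t1, pars$pair_axial, M, cfg)
  }
  t1
}

#' Run the mutual interaction block
#'
#' @param state List with nodes `z`, `t`, `p` and sizes `M`, `N`.
#' @param iters List of per-iteration parameter sets (untied weights).
#' @param cfg A `pd_config`.
#' @return State with updated `z` and `t` (`p` unchanged).
#' @export
mutual_interaction <- function(state, iters, cfg) {
  for (pars in iters) {
    if (cfg$use_complex_triangular) {
      state$z <- complex_triangular_update(state, pars$ctri)
    }
    if (cfg$use_complex_axial) {
      state$z <- complex_axial_attention(state, pars, cfg)
    }
    if (cfg$use_complex_to_ligand) {
      state$t <- complex_to_ligand_communication(state, pars, cfg)
    }
  }
  state
}
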