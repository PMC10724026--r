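# Atom-pair attentive encoding block.
#
# A molecule encoder initializes per-atom embeddings from one-hot features
# and per-pair embeddings from a pair-type aware Gaussian encoding of the
# interatomic distances (plus bond features for the ligand), then applies
# n_blocks repetitions of [atom attention -> self-triangular update ->
# pair axial attention]. Everything downstream sees only distances and
# topology, so the encoding is invariant to rigid motions of the input
# coordinates. Pre-LN residual plumbing throughout.

#' Initialize atom embeddings from one-hot features
#'
#' Linear embedding without bias: `m_i = W_h h_i`.
#' @param feats M x d_feat one-hot matrix (plain numeric).
#' @param W_h Embedding weights, `list(W, b = NULL)`.
#' @return `adnode`, M x d_atom.
#' @export
init_atom_embedding <- function(feats, W_h) {
  ad_linear(ad_const(feats), W_h$W, NULL)
}

#' Initialize pair embeddings from coordinates and bonds
#'
#' Pair-type aware affine transform of the Euclidean distance, a bank of
#' learnable Gaussian channels, a linear projection to `d_pair`, plus an
#' additive bond-feature embedding for bonded pairs (zero otherwise).
#'
#' @param coords n x 3 coordinates (Angstrom).
#' @param elements Element symbols (pair types are unordered element pairs).
#' @param gauss List of parameter leaves `a`, `b`, `mu`, `sigma`.
#' @param W_t Projection from Gaussian channels to `d_pair`.
#' @param bond_features Optional (n*n) x d_bond matrix (flattened row-major).
#' @param W_e Optional bond embedding weights.
#' @return `adnode`, (n*n) x d_pair.
#' @export
init_pair_embedding <- function(coords, elements, gauss, W_t,
                                bond_features = NULL, W_e = NULL) {
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  n <- nrow(coords)
  d <- as.vector(t(as.matrix(stats::dist(coords))))  # row-major, d_ii = 0
  full <- expand.grid(k = seq_len(n), i = seq_len(n))  # k fastest = row-major
  ptype <- pd_pair_type(elements[full$i], elements[full$k])
  basis <- ad_gauss_basis(d, ptype, gauss$a, gauss$b, gauss$mu, gauss$sigma)
  t0 <- apply_lin(basis, W_t)
  if (!is.null(bond_features) && !is.null(W_e)) {
    t0 <- ad_add(t0, ad_linear(ad_const(bond_features), W_e$W, NULL))
  }
  t0
}

#' Atom attention layer
#'
#' Multi-head self-attention over atoms with the pair embedding projected
#' into a per-head additive logit bias; the per-head pre-softmax logits are
#' projected back to update the pair embedding. Residual feed-forward
#' sublayer on the atom track.
#'
#' @param m Atom embedding node (n x d_atom).
#' @param t Pair embedding node ((n*n) x d_pair).
#' @param pars Layer parameters (see `mha_pars`).
#' @param cfg A `pd_config`.
#' @return List `(m, t)` of updated nodes.
#' @export
atom_attention <- function(m, t, pars, cfg) {
  n <- nrow(ad_val(m))
  H <- cfg$n_heads
  dh <- cfg$d_atom %/% H
  mn <- apply_ln(m, pars$ln)
  tn <- apply_ln(t, pars$ln_pair)
  Q <- apply_lin(mn, pars$q); K <- apply_lin(mn, pars$k)
  V <- apply_lin(mn, pars$v)
  bias_all <- ad_linear(tn, pars$bias$W, NULL)  # (n*n) x H
  outs <- vector("list", H)
  logits <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ad_slice_cols(Q, cols)
    Kh <- ad_slice_cols(K, cols)
    Vh <- ad_slice_cols(V, cols)
    S <- ad_scale(ad_matmul(Qh, Kh, tb = TRUE), 1 / sqrt(dh))
    logit <- ad_add(S, ad_col_as_mat(bias_all, h, n, n))
    logits[[h]] <- logit
    outs[[h]] <- ad_matmul(ad_softmax_rows(logit), Vh)
  }
  m1 <- ad_add(m, apply_lin(ad_concat_cols(outs), pars$o))
  t1 <- ad_add(t, apply_lin(ad_mats_as_cols(logits, n, n), pars$logit2pair))
  list(m = m1, t = t1)
}

atom_ffn <- function(m, pars) {
  ad_add(m, apply_lin(ad_gelu(apply_lin(apply_ln(m, pars$ln), pars$w1)),
                      pars$w2))
}

#' Self-triangular multiplicative update
#'
#' Each pair (i,k) aggregates products over the two other edges of every
#' triangle through a third atom l — outgoing (il, kl) and incoming (li, lk)
#' edges are summed inside one update; the sum index l ranges over all atoms
#' including i and k. Gated residual output.
#'
#' @param t Pair node ((n*n) x d_pair).
#' @param pars Parameters (see `tri_pars`).
#' @param n Number of atoms.
#' @return Updated pair node.
#' @export
self_triangular_update <- function(t, pars, n) {
  tn <- apply_ln(t, pars$ln)
  a <- apply_glu(tn, pars$a)
  b <- apply_glu(tn, pars$b)
  s <- ad_add(ad_chan_matmul(a, b, n, n, n, n, tb = TRUE),   # sum_l a_il b_kl
              ad_chan_matmul(a, b, n, n, n, n, ta = TRUE))   # sum_l a_li b_lk
  g <- ad_sigmoid(apply_lin(tn, pars$g))
  ad_add(t, ad_mul(g, apply_lin(s, pars$out)))
}

#' Pair axial attention
#'
#' Each pair (i,k) attends over the third index l with logits combining the
#' same-row key K_il and same-column key K_lk in a single softmax, biased by
#' the third-edge terms b_kl and b_li; values aggregate V_il + V_lk, gated,
#' projected, residual.
#'
#' @inheritParams self_triangular_update
#' @param cfg A `pd_config` (supplies the head count).
#' @return Updated pair node.
#' @export
pair_axial_attention <- function(t, pars, n, cfg) {
  tn <- apply_ln(t, pars$ln)
  q <- apply_lin(tn, pars$q); k <- apply_lin(tn, pars$k)
  v <- apply_lin(tn, pars$v)
  bias <- ad_linear(tn, pars$bias$W, NULL)
  u <- ad_pair_axial(q, k, v, bias, n, cfg$n_heads)
  g <- ad_sigmoid(apply_lin(tn, pars$gate))
  ad_add(t, apply_lin(ad_mul(g, u), pars$o))
}

#' Encode one molecule
#'
#' @param pars Encoder parameters (ligand or pocket weights).
#' @param cfg A `pd_config`.
#' @param feats Atom one-hot matrix.
#' @param coords n x 3 coordinates of the conformer to encode.
#' @param elements Element symbols.
#' @param bond_features Optional flattened bond one-hot matrix (ligand).
#' @return List with nodes `atoms` (n x d_atom) and `pairs` ((n*n) x d_pair).
#' @export
encode_molecule <- function(pars, cfg, feats, coords, elements,
                            bond_features = NULL) {
  n <- nrow(feats)
  m <- init_atom_embedding(feats, pars$W_h)
  t <- init_pair_embedding(coords, elements, pars$gauss, pars$W_t,
                           bond_features, pars$W_e)
  for (blk in pars$blocks) {
    upd <- atom_attention(m, t, blk$attn, cfg)
    m <- atom_ffn(upd$m, blk$ffn)
    t <- upd$t
    if (cfg$use_self_triangular) t <- self_triangular_update(t, blk$tri, n)
    if (cfg$use_pair_axial) t <- pair_axial_attention(t, blk$axial, n, cfg)
  }
  list(atoms = m, pairs = t)
}
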