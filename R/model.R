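# Model assembly: parameter initialization and the full forward pass.
#
# Weight layout convention: a "linear" is list(W, b) of ad_param leaves
# (b NULL when absent). Residual-branch output projections are initialized
# at 1/10 Glorot scale so every block starts close to the identity (stable
# early training) while still passing gradient to its whole branch; all
# other weights are Glorot-uniform.

lin_pars <- function(d_in, d_out, bias = TRUE, scale = 1) {
  s <- scale * sqrt(6 / (d_in + d_out))
  W <- matrix(stats::runif(d_in * d_out, -s, s), d_in, d_out)
  list(W = ad_param(W), b = if (bias) ad_param(numeric(d_out)) else NULL)
}

ln_pars <- function(d) list(g = ad_param(rep(1, d)), b = ad_param(numeric(d)))

apply_lin <- function(x, p) ad_linear(x, p$W, p$b)
apply_ln <- function(x, p) ad_layernorm(x, p$g, p$b)

# gated linear unit per Eqs 7/16-19/26: sigmoid(Linear(x)) * Linear(x)
glu_pars <- function(d_in, d_out) {
  list(gate = lin_pars(d_in, d_out), val = lin_pars(d_in, d_out))
}
apply_glu <- function(x, p) {
  ad_mul(ad_sigmoid(apply_lin(x, p$gate)), apply_lin(x, p$val))
}

mha_pars <- function(d_model, d_pair, H, with_bias_proj = TRUE) {
  p <- list(ln = ln_pars(d_model),
            q = lin_pars(d_model, d_model), k = lin_pars(d_model, d_model),
            v = lin_pars(d_model, d_model),
            o = lin_pars(d_model, d_model, scale = 0.1))
  if (with_bias_proj) {
    p$ln_pair <- ln_pars(d_pair)
    p$bias <- lin_pars(d_pair, H, bias = FALSE)
    p$logit2pair <- lin_pars(H, d_pair, scale = 0.1)
  }
  p
}

tri_pars <- function(d_pair) {
  list(ln = ln_pars(d_pair),
       a = glu_pars(d_pair, d_pair), b = glu_pars(d_pair, d_pair),
       g = lin_pars(d_pair, d_pair),
       out = lin_pars(d_pair, d_pair, scale = 0.1))
}

axial_pars <- function(d_pair, H) {
  list(ln = ln_pars(d_pair),
       q = lin_pars(d_pair, d_pair), k = lin_pars(d_pair, d_pair),
       v = lin_pars(d_pair, d_pair),
       bias = lin_pars(d_pair, H, bias = FALSE),
       gate = lin_pars(d_pair, d_pair),
       o = lin_pars(d_pair, d_pair, scale = 0.1))
}

ffn_pars <- function(d, mult) {
  list(ln = ln_pars(d), w1 = lin_pars(d, d * mult),
       w2 = lin_pars(d * mult, d, scale = 0.1))
}

enc_block_pars <- function(cfg) {
  p <- list(attn = mha_pars(cfg$d_atom, cfg$d_pair, cfg$n_heads),
            ffn = ffn_pars(cfg$d_atom, cfg$ffn_mult))
  if (cfg$use_self_triangular) p$tri <- tri_pars(cfg$d_pair)
  if (cfg$use_pair_axial) p$axial <- axial_pars(cfg$d_pair, cfg$n_heads)
  p
}

encoder_pars <- function(cfg, d_feat, with_bonds) {
  dims <- pd_feature_dims()
  p <- list(
    W_h = lin_pars(d_feat, cfg$d_atom, bias = FALSE),
    gauss = list(a = ad_param(rep(1, dims$n_pair_types)),
                 b = ad_param(numeric(dims$n_pair_types)),
                 mu = ad_param(seq(0, 15, length.out = cfg$n_gauss)),
                 sigma = ad_param(rep(2, cfg$n_gauss))),
    W_t = lin_pars(cfg$n_gauss, cfg$d_pair),
    blocks = lapply(seq_len(cfg$n_blocks), function(i) enc_block_pars(cfg))
  )
  if (with_bonds) p$W_e <- lin_pars(dims$bond, cfg$d_pair, bias = FALSE)
  p
}

caxial_branch_pars <- function(d_pair) {
  list(ln = ln_pars(d_pair),
       q = lin_pars(d_pair, d_pair), k = lin_pars(d_pair, d_pair),
       v = lin_pars(d_pair, d_pair),
       gate = lin_pars(d_pair, d_pair),
       o = lin_pars(d_pair, d_pair, scale = 0.1))
}

inter_iter_pars <- function(cfg) {
  d <- cfg$d_pair
  p <- list()
  if (cfg$use_complex_triangular) {
    p$ctri <- list(ln_z = ln_pars(d), ln_t = ln_pars(d), ln_p = ln_pars(d),
                   a = glu_pars(d, d), b = glu_pars(d, d),
                   tg = glu_pars(d, d), pg = glu_pars(d, d),
                   g = lin_pars(d, d), out = lin_pars(d, d, scale = 0.1))
  }
  if (cfg$use_complex_axial) {
    p$crow <- caxial_branch_pars(d)
    p$ccol <- caxial_branch_pars(d)
  }
  if (cfg$use_complex_to_ligand) {
    p$comm <- list(ln_z = ln_pars(d), ln_t = ln_pars(d),
                   g = lin_pars(d, d), out = lin_pars(d, d, scale = 0.1))
    if (cfg$use_self_triangular) p$pair_tri <- tri_pars(d)
    if (cfg$use_pair_axial) p$pair_axial <- axial_pars(d, cfg$n_heads)
  }
  p
}

head_pars <- function(cfg) {
  d <- cfg$d_pair; da <- cfg$d_atom
  list(ln_t = ln_pars(d), ln_z = ln_pars(d),
       d_lig = lin_pars(d, 1L), d_inter = lin_pars(d, 1L),
       ln_m = ln_pars(da), ln_n = ln_pars(da),
       aff_glu = glu_pars(d + 2L * da, d),
       aff_out = lin_pars(d, 1L))
}

#' Initialize a model
#'
#' Creates all trainable parameters (pocket and ligand encoders share the
#' architecture but have independent weights).
#'
#' @param cfg A [pd_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `pd_model` with elements `cfg` and `params`.
#' @export
pd_model <- function(cfg = pd_config(), seed = 1L) {
  stopifnot(inherits(cfg, "pd_config"))
  set.seed(seed)
  dims <- pd_feature_dims()
  params <- list(
    lig_enc = encoder_pars(cfg, dims$ligand_atom, with_bonds = TRUE),
    poc_enc = encoder_pars(cfg, dims$pocket_atom, with_bonds = FALSE),
    z_init = lin_pars(cfg$d_atom^2, cfg$d_pair),
    inter = lapply(seq_len(cfg$n_iter), function(i) inter_iter_pars(cfg)),
    heads = head_pars(cfg)
  )
  structure(list(cfg = cfg, params = params), class = "pd_model")
}

#' Number of trainable scalars in a model
#' @param model A `pd_model`.
#' @return Integer parameter count.
#' @export
pd_n_params <- function(model) {
  sum(vapply(ad_collect_params(model$params),
             function(p) length(p$value), numeric(1)))
}

#' @export
print.pd_model <- function(x, ...) {
  cat(sprintf("<pd_model> %s parameters\n",
              format(pd_n_params(x), big.mark = ",")))
  print(x$cfg)
  invisible(x)
}

#' Full forward pass for one pocket-ligand complex
#'
#' Encodes ligand and pocket, initializes the complex pair tensor from the
#' outer product of the atom embeddings, runs the mutual-interaction
#' iterations and applies the prediction heads.
#'
#' @param model A [pd_model()].
#' @param lig A [ligand_record()] with at least one conformer.
#' @param poc A [pocket_record()].
#' @param conformer Index of the ligand conformer to condition on.
#' @return List with numeric results `D_lig` (M x M, symmetrized, Angstrom),
#'   `D_inter` (M x N), `affinity` (scalar) and the underlying tape nodes
#'   under `nodes` (for loss construction).
#' @export
pd_forward <- function(model, lig, poc, conformer = 1L) {
  cfg <- model$cfg; pp <- model$params
  stopifnot(inherits(lig, "ligand_record"), inherits(poc, "pocket_record"))
  if (length(lig$conformers) < conformer) {
    stop("ligand has no conformer ", conformer)
  }
  M <- lig$atom_count; N <- poc$atom_count

  enc_l <- encode_molecule(pp$lig_enc, cfg,
                           feats = lig$atom_features,
                           coords = lig$conformers[[conformer]],
                           elements = lig$mol$elements,
                           bond_features = lig$bond_features)
  enc_p <- encode_molecule(pp$poc_enc, cfg,
                           feats = poc$atom_features,
                           coords = poc$coords,
                           elements = poc$elements,
                           bond_features = NULL)

  z0 <- apply_lin(ad_outer_rows(enc_l$atoms, enc_p$atoms), pp$z_init)
  st <- mutual_interaction(list(z = z0, t = enc_l$pairs, p = enc_p$pairs,
                                M = M, N = N),
                           pp$inter, cfg)
  out <- prediction_heads(pp$heads, cfg, st$z, st$t,
                          enc_l$atoms, enc_p$atoms, M, N)
  list(
    D_lig = matrix(ad_val(out$D_lig), M, M, byrow = TRUE),
    D_inter = matrix(ad_val(out$D_inter), M, N, byrow = TRUE),
    affinity = as.numeric(ad_val(out$affinity)),
    nodes = c(out, list(m = enc_l$atoms, n = enc_p$atoms,
                        t = st$t, z = st$z))
  )
}
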