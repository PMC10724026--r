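# Model / training configuration.

#' Model and training configuration
#'
#' Defaults mirror common practice for this model family; the pair and atom
#' widths, head/block counts and interaction depth are freely overridable
#' (tests and the worked examples use reduced sizes).
#'
#' @param d_atom Atom embedding width (divisible by `n_heads`).
#' @param d_pair Pair embedding width (divisible by `n_heads`).
#' @param n_gauss Number of Gaussian distance-encoding channels.
#' @param n_heads Attention heads (atom, pair-axial and complex-axial).
#' @param n_blocks Encoding blocks per molecule encoder.
#' @param n_iter Mutual-interaction iterations (untied weights).
#' @param ffn_mult Feed-forward expansion factor in the atom track.
#' @param use_self_triangular,use_pair_axial Ablation switches for the two
#'   pair-attention submodules (applied wherever the submodule occurs).
#' @param use_complex_triangular,use_complex_axial,use_complex_to_ligand
#'   Ablation switches for the three interaction-block layers.
#' @param alpha,beta,gamma Loss weights: intermolecular distances, ligand
#'   distances, affinity.
#' @param delta1,delta2 Pose-generation loss weights (inter / intra terms).
#' @param lr Adam learning rate for training.
#' @param pose_lr,pose_steps,pose_restarts,pose_init_sd Pose optimization:
#'   Adam step size, iterations, independent restarts, and the s.d. (in
#'   Angstrom) of the Gaussian initialization around the pocket centroid.
#' @param auto_zero_gamma Zero the affinity term when a label is missing
#'   instead of erroring.
#' @return Object of class `pd_config`.
#' @export
pd_config <- function(d_atom = 128L, d_pair = 64L, n_gauss = 16L,
                      n_heads = 8L, n_blocks = 4L, n_iter = 4L,
                      ffn_mult = 4L,
                      use_self_triangular = TRUE, use_pair_axial = TRUE,
                      use_complex_triangular = TRUE,
                      use_complex_axial = TRUE,
                      use_complex_to_ligand = TRUE,
                      alpha = 1, beta = 1, gamma = 1,
                      delta1 = 1, delta2 = 1,
                      lr = 1e-3,
                      pose_lr = 0.1, pose_steps = 1000L, pose_restarts = 4L,
                      pose_init_sd = 3,
                      auto_zero_gamma = FALSE) {
  stopifnot(d_atom %% n_heads == 0L, d_pair %% n_heads == 0L,
            n_gauss >= 1L, n_blocks >= 0L, n_iter >= 1L,
            alpha >= 0, beta >= 0, gamma >= 0, alpha + beta + gamma > 0,
            delta1 >= 0, delta2 >= 0, lr > 0)
  structure(as.list(environment()), class = "pd_config")
}

#' Read a configuration from a YAML file
#'
#' Keys mirror the arguments of [pd_config()]; unknown keys error.
#' @param path YAML file path.
#' @return A `pd_config`.
#' @export
pd_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pd_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pd_config, vals)
}

#' @export
print.pd_config <- function(x, ...) {
  cat(sprintf(paste0("<pd_config> d_atom=%d d_pair=%d heads=%d gauss=%d ",
                     "blocks=%d iters=%d\n"),
              x$d_atom, x$d_pair, x$n_heads, x$n_gauss, x$n_blocks, x$n_iter))
  off <- c("self_triangular", "pair_axial", "complex_triangular",
           "complex_axial", "complex_to_ligand")
  off <- off[!unlist(x[paste0("use_", off)])]
  if (length(off)) cat("  ablated:", paste(off, collapse = ", "), "\n")
  invisible(x)
}
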