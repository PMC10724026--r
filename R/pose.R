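# Ligand coordinate generation from predicted distance maps.
#
# Coordinates are recovered by minimizing an L1 discrepancy between the
# current Euclidean distances and the predicted intermolecular /
# intra-ligand distance maps, by Adam gradient descent from seeded random
# starts around the pocket centroid; the lowest-loss restart wins. The
# pocket anchors the frame (and the chirality) of the solution.

#' Distance-map discrepancy of a candidate pose
#'
#' `delta1 * mean_ij |d(x_i, p_j) - D_inter_ij| +
#'  delta2 * mean_ik |d(x_i, x_k) - D_lig_ik|`
#' (full matrices, diagonal included). Invariant to joint rigid transforms
#' of ligand and pocket.
#'
#' @param x_lig M x 3 candidate ligand coordinates.
#' @param x_poc N x 3 pocket coordinates.
#' @param D_inter M x N predicted intermolecular distances (Angstrom).
#' @param D_lig M x M predicted intra-ligand distances.
#' @param delta1,delta2 Term weights.
#' @return Scalar loss.
#' @export
coords_loss <- function(x_lig, x_poc, D_inter, D_lig, delta1 = 1, delta2 = 1) {
  di <- cross_dist(x_lig, x_poc)
  dl <- cross_dist(x_lig, x_lig)
  delta1 * mean(abs(di - D_inter)) + delta2 * mean(abs(dl - D_lig))
}

coords_loss_grad <- function(x_lig, x_poc, D_inter, D_lig, delta1, delta2) {
  M <- nrow(x_lig); N <- nrow(x_poc)
  g <- matrix(0, M, 3L)
  di <- cross_dist(x_lig, x_poc)
  w <- delta1 * sign(di - D_inter) / (M * N) / pmax(di, 1e-9)
  w[di < 1e-9] <- 0
  g <- g + rowSums(w) * x_lig - w %*% x_poc
  dl <- cross_dist(x_lig, x_lig)
  wl <- delta2 * sign(dl - D_lig) / (M * M) / pmax(dl, 1e-9)
  wl[dl < 1e-9] <- 0
  wt <- wl + t(wl)   # both orderings of each pair touch x_i
  g + rowSums(wt) * x_lig - wt %*% x_lig
}

#' Generate a ligand pose from predicted distance maps
#'
#' Coordinates are initialized from a Gaussian centred at the pocket
#' centroid and optimized by Adam for `n_steps`; `n_restarts` independent
#' seeded starts are run and the lowest-loss result returned.
#' Non-convergence is not an error: the best pose found is returned with
#' its loss.
#'
#' @param x_poc N x 3 pocket coordinates (>= 4 non-coplanar atoms for a
#'   well-posed problem).
#' @param D_inter,D_lig Predicted distance maps (Angstrom).
#' @param delta1,delta2 Loss weights.
#' @param seed Integer seed (restart r uses `seed + r`).
#' @param n_steps Adam iterations per restart.
#' @param n_restarts Independent restarts.
#' @param lr Adam step size.
#' @param init_sd S.d. of the Gaussian initialization (Angstrom).
#' @param conformer_index Bookkeeping tag stored in the result.
#' @return Object of class `pose_result`: `coords`, `final_loss`,
#'   `conformer_index`, `n_steps`.
#' @export
generate_pose <- function(x_poc, D_inter, D_lig, delta1 = 1, delta2 = 1,
                          seed = 1L, n_steps = 1000L, n_restarts = 4L,
                          lr = 0.1, init_sd = 3, conformer_index = 1L) {
  M <- nrow(D_inter)
  stopifnot(ncol(D_inter) == nrow(x_poc), nrow(D_lig) == M, ncol(D_lig) == M)
  centroid <- colMeans(x_poc)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    x <- matrix(stats::rnorm(M * 3L, sd = init_sd), M, 3L) +
      rep(centroid, each = M)
    mstate <- matrix(0, M, 3L); vstate <- matrix(0, M, 3L)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (it in seq_len(n_steps)) {
      g <- coords_loss_grad(x, x_poc, D_inter, D_lig, delta1, delta2)
      mstate <- b1 * mstate + (1 - b1) * g
      vstate <- b2 * vstate + (1 - b2) * g * g
      mh <- mstate / (1 - b1^it)
      vh <- vstate / (1 - b2^it)
      x <- x - lr * mh / (sqrt(vh) + eps)
    }
    l <- coords_loss(x, x_poc, D_inter, D_lig, delta1, delta2)
    if (is.null(best) || l < best$final_loss) {
      best <- structure(list(coords = x, final_loss = l,
                             conformer_index = conformer_index,
                             n_steps = n_steps),
                        class = "pose_result")
    }
  }
  best
}

#' Select the final prediction across conformer-conditioned runs
#'
#' Picks the pose with the lowest generation loss; ties break to the lowest
#' conformer index (list order).
#'
#' @param results Non-empty list of `pose_result`s.
#' @param affinities Optional numeric vector aligned with `results`.
#' @return List with `pose` (the winning `pose_result`), `affinity` (or
#'   `NA` if none supplied) and `index`.
#' @export
select_prediction <- function(results, affinities = NULL) {
  if (!length(results)) stop("no pose results to select from")
  losses <- vapply(results, function(r) r$final_loss, numeric(1))
  idx <- which.min(losses)   # first minimum: lowest index on ties
  list(pose = results[[idx]],
       affinity = if (is.null(affinities)) NA_real_ else affinities[idx],
       index = idx)
}

#' @export
print.pose_result <- function(x, ...) {
  cat(sprintf("<pose_result> %d atoms, generation loss %.4f (conformer %d)\n",
              nrow(x$coords), x$final_loss, x$conformer_index))
  invisible(x)
}
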