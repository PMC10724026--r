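# Training loop, inference pipeline and evaluation metrics.

adam_new <- function(leaves) {
  list(leaves = leaves,
       m = lapply(leaves, function(p) array(0, dim = dim(as.matrix(p$value)))),
       v = lapply(leaves, function(p) array(0, dim = dim(as.matrix(p$value)))),
       t = 0L)
}

adam_step <- function(opt, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (i in seq_along(opt$leaves)) {
    p <- opt$leaves[[i]]
    g <- p$grad
    if (is.null(g)) next
    g <- array(g, dim = dim(as.matrix(p$value)))
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mh <- opt$m[[i]] / (1 - b1^opt$t)
    vh <- opt$v[[i]] / (1 - b2^opt$t)
    upd <- lr * mh / (sqrt(vh) + eps)
    p$value <- p$value - if (is.null(dim(p$value))) as.vector(upd) else upd
  }
  opt
}

complex_truth <- function(cx) {
  maps <- true_distance_maps(cx$ligand$holo_coords, cx$pocket$coords)
  maps$affinity <- cx$ligand$affinity
  maps
}

#' Train a model on preprocessed complexes
#'
#' One step is an Adam update on the mean loss over all complexes (one
#' training epoch at this scale). Each epoch independently resamples one
#' apo conformer per complex from its representative set, so the model
#' learns to map any unbound conformation to the bound-state distance
#' maps. Fully deterministic given `seed`.
#'
#' @param complexes List of complexes, each `list(ligand, pocket)` with a
#'   holo pose (and affinity label unless `gamma = 0`).
#' @param cfg A [pd_config()].
#' @param model Optional existing [pd_model()] to continue training.
#' @param steps Number of optimizer steps (epochs).
#' @param seed Integer seed (weights, conformer sampling).
#' @param validation Optional held-out complexes; tracked every
#'   `val_every` steps and the best-validation parameters are restored at
#'   the end.
#' @param val_every Validation period in steps.
#' @param checkpoint Optional path; the returned model is also serialized
#'   there via [pd_save_checkpoint()].
#' @param verbose Print progress every 50 steps.
#' @return List with `model`, `history` (per-step training loss),
#'   `conformer_draws` (steps x complexes matrix of sampled conformer
#'   indices) and `val_history`.
#' @export
pd_train <- function(complexes, cfg = pd_config(), model = NULL,
                     steps = 500L, seed = 1L, validation = NULL,
                     val_every = 25L, checkpoint = NULL, verbose = FALSE) {
  if (!length(complexes)) stop("empty training set")
  if (is.null(model)) model <- pd_model(cfg, seed = seed)
  truths <- lapply(complexes, complex_truth)
  leaves <- ad_collect_params(model$params)
  opt <- adam_new(leaves)
  set.seed(seed + 1L)
  history <- numeric(steps)
  val_history <- rep(NA_real_, steps)
  draws <- matrix(0L, steps, length(complexes))
  best_val <- Inf; best_values <- NULL
  for (s in seq_len(steps)) {
    draws[s, ] <- vapply(complexes, function(cx) {
      sample.int(length(cx$ligand$conformers), 1L)
    }, integer(1))
    ad_reset()
    ad_zero_grad(leaves)
    losses <- lapply(seq_along(complexes), function(ci) {
      fw <- pd_forward(model, complexes[[ci]]$ligand, complexes[[ci]]$pocket,
                       conformer = draws[s, ci])
      total_loss(fw$nodes, truths[[ci]], cfg)
    })
    loss <- losses[[1L]]
    if (length(losses) > 1L) for (l in losses[-1L]) loss <- ad_add(loss, l)
    loss <- ad_scale(loss, 1 / length(losses))
    history[s] <- as.numeric(ad_val(loss))
    ad_backward(loss)
    opt <- adam_step(opt, cfg$lr)
    if (!is.null(validation) && (s %% val_every == 0L || s == steps)) {
      vl <- pd_eval_loss(model, validation, cfg)
      val_history[s] <- vl
      if (vl < best_val) {
        best_val <- vl
        best_values <- lapply(leaves, function(p) p$value)
      }
    }
    if (verbose && s %% 50L == 0L) {
      message(sprintf("step %d loss %.4f", s, history[s]))
    }
  }
  if (!is.null(best_values)) {
    for (i in seq_along(leaves)) leaves[[i]]$value <- best_values[[i]]
  }
  ad_reset()
  if (!is.null(checkpoint)) pd_save_checkpoint(model, checkpoint)
  list(model = model, history = history, conformer_draws = draws,
       val_history = val_history)
}

pd_eval_loss <- function(model, complexes, cfg) {
  mark <- .ad$n
  out <- mean(vapply(complexes, function(cx) {
    fw <- pd_forward(model, cx$ligand, cx$pocket, conformer = 1L)
    as.numeric(ad_val(total_loss(fw$nodes, complex_truth(cx), cfg)))
  }, numeric(1)))
  .ad$n <- mark   # drop evaluation nodes from the tape
  out
}

#' Predict pose and affinity for one pocket-ligand pair
#'
#' Runs the network once per apo conformer, reconstructs coordinates from
#' each conformer's predicted distance maps, and returns the result with
#' the lowest generation loss together with its predicted affinity.
#'
#' @param model A trained [pd_model()].
#' @param lig A [ligand_record()] with conformers.
#' @param poc A [pocket_record()].
#' @param seed Integer seed for pose initialization.
#' @return List with `pose` (a `pose_result`), `affinity`, `conformer`
#'   (winning index) and `per_conformer` (data frame: conformer,
#'   generation_loss, affinity).
#' @export
pd_predict <- function(model, lig, poc, seed = 1L) {
  cfg <- model$cfg
  if (!length(lig$conformers)) stop("ligand record has no conformers")
  results <- vector("list", length(lig$conformers))
  affs <- numeric(length(lig$conformers))
  for (ci in seq_along(lig$conformers)) {
    mark <- .ad$n
    fw <- pd_forward(model, lig, poc, conformer = ci)
    .ad$n <- mark
    results[[ci]] <- generate_pose(
      poc$coords, fw$D_inter, fw$D_lig,
      delta1 = cfg$delta1, delta2 = cfg$delta2,
      seed = seed + 1000L * ci, n_steps = cfg$pose_steps,
      n_restarts = cfg$pose_restarts, lr = cfg$pose_lr,
      init_sd = cfg$pose_init_sd, conformer_index = ci)
    affs[ci] <- fw$affinity
  }
  sel <- select_prediction(results, affs)
  list(pose = sel$pose, affinity = sel$affinity, conformer = sel$index,
       per_conformer = data.frame(
         conformer = seq_along(results),
         generation_loss = vapply(results, `[[`, numeric(1), "final_loss"),
         affinity = affs))
}

#' Ligand RMSD without superposition
#'
#' Root-mean-square deviation of atomic coordinates in the pocket frame
#' (same atom ordering, no alignment).
#' @param pred,truth M x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  sqrt(mean(rowSums((pred - truth)^2)))
}

#' Evaluate pose and affinity predictions
#'
#' @param pred_coords,true_coords Lists of M x 3 matrices (same ordering).
#' @param pred_affinity,true_affinity Optional numeric vectors (pK).
#' @param thresholds RMSD success thresholds in Angstrom.
#' @param rmsd Optional precomputed per-complex RMSD vector (used instead
#'   of the coordinate lists).
#' @return List of class `eval_report`: `rmsd` (per complex), `percentiles`
#'   (25/50/75), `mean_rmsd`, `pct_below` (per threshold, in percent),
#'   and affinity `mae`, `rmse`, `pearson`, `spearman` (NA with a warning
#'   if undefined).
#' @export
evaluate_predictions <- function(pred_coords = NULL, true_coords = NULL,
                                 pred_affinity = NULL, true_affinity = NULL,
                                 thresholds = c(2, 5), rmsd = NULL) {
  if (is.null(rmsd) && !is.null(pred_coords)) {
    stopifnot(length(pred_coords) == length(true_coords))
    rmsd <- mapply(ligand_rmsd, pred_coords, true_coords)
  }
  rep_ <- if (is.null(rmsd)) list() else list(
    rmsd = rmsd,
    percentiles = stats::quantile(rmsd, c(0.25, 0.5, 0.75)),
    mean_rmsd = mean(rmsd),
    pct_below = stats::setNames(
      vapply(thresholds, function(th) 100 * mean(rmsd < th), numeric(1)),
      paste0("<", thresholds, "A"))
  )
  if (!is.null(pred_affinity)) {
    stopifnot(length(pred_affinity) == length(true_affinity))
    rep_$mae <- mean(abs(pred_affinity - true_affinity))
    rep_$rmse <- sqrt(mean((pred_affinity - true_affinity)^2))
    if (stats::sd(pred_affinity) == 0 || stats::sd(true_affinity) == 0) {
      warning("constant affinities: correllation undefined, reported as NA")
      rep_$pearson <- NA_real_
      rep_$spearman <- NA_real_
    } else {
      rep_$pearson <- stats::cor(pred_affinity, true_affinity)
      rep_$spearman <- stats::cor(pred_affinity, true_affinity,
                                  method = "spearman")
    }
  }
  structure(rep_, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (!is.null(x$rmsd)) {
    cat(sprintf("<eval_report> n=%d  RMSD mean %.3f A (25/50/75%%: %.3f/%.3f/%.3f)\n",
                length(x$rmsd), x$mean_rmsd,
                x$percentiles[1], x$percentiles[2], x$percentiles[3]))
    cat("  success:",
        paste(sprintf("%s %.1f%%", names(x$pct_below), x$pct_below),
              collapse = ", "), "\n")
  } else {
    cat("<eval_report>\n")
  }
  if (!is.null(x$mae)) {
    cat(sprintf("  affinity MAE %.3f RMSE %.3f Pearson %.3f Spearman %.3f\n",
                x$mae, x$rmse, x$pearson, x$spearman))
  }
  invisible(x)
}
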