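# Prediction heads and the three-part smooth-L1 objective.

ad <- function(name) get(name, envir = asNamespace("pairdock"))
aconst <- function(x) ad("ad_const")(x)
aval <- function(x) ad("ad_val")(x)

test_that("smooth_l1 reproduces its branch values and is continuous", {
  expect_equal(smooth_l1(1, 1), 0)
  expect_equal(smooth_l1(0.5, 0), 0.125)
  expect_equal(smooth_l1(3, 0), 2.5)
  # continuity at the branch point: both branches give 0.5
  expect_equal(0.5 * 1^2, 1 - 0.5)
  eps <- 1e-9
  expect_equal(smooth_l1(1 - eps, 0), smooth_l1(1 + eps, 0), tolerance = 1e-8)
  # elementwise on matrices
  expect_equal(smooth_l1(matrix(c(0.5, 3), 1), matrix(0, 1, 2)),
               matrix(c(0.125, 2.5), 1))
})

test_that("distance head output is exactly symmetric and matches a dot-product oracle", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 30)
  hp <- model$params$heads
  M <- 4L; N <- 3L
  set.seed(40)
  tl <- rand_pair(M, M, cfg$d_pair)
  z <- rand_pair(M, N, cfg$d_pair)
  out <- predict_distances(hp, aconst(tl), aconst(z), M, N)
  D <- matrix(aval(out$D_lig), M, M, byrow = TRUE)
  expect_identical(D, t(D))
  # per-element oracle: raw head is a dot product on the normalized pair row
  tn <- ref_ln(tl, hp$ln_t)
  raw <- tn %*% hp$d_lig$W$value + hp$d_lig$b$value
  want <- 0.5 * (matrix(raw, M, M, byrow = TRUE) +
                   t(matrix(raw, M, M, byrow = TRUE)))
  expect_lt(max(abs(D - want)), 1e-8)
  # constant head: zero weights leave only the bias
  hp$d_inter$W$value[] <- 0
  out2 <- predict_distances(hp, aconst(tl), aconst(z), M, N)
  expect_equal(as.vector(aval(out2$D_inter)),
               rep(hp$d_inter$b$value, M * N))
})

test_that("affinity head equals the loop-computed pooled mean", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 31)
  hp <- model$params$heads
  M <- 3L; N <- 4L
  set.seed(41)
  z <- rand_pair(M, N, cfg$d_pair)
  m <- matrix(stats::rnorm(M * cfg$d_atom), M)
  n <- matrix(stats::rnorm(N * cfg$d_atom), N)
  got <- as.numeric(aval(predict_affinity(hp, aconst(z), aconst(m),
                                          aconst(n), M, N)))
  want <- ref_affinity(z, m, n, hp, M, N)
  expect_equal(got, want, tolerance = 1e-8)
  # pooling identities: M = N = 1 and all-equal rows
  g1 <- as.numeric(aval(predict_affinity(hp, aconst(z[1, , drop = FALSE]),
                                         aconst(m[1, , drop = FALSE]),
                                         aconst(n[1, , drop = FALSE]), 1L, 1L)))
  expect_equal(g1, ref_affinity(z[1, , drop = FALSE], m[1, , drop = FALSE],
                                n[1, , drop = FALSE], hp, 1L, 1L),
               tolerance = 1e-8)
})

test_that("total loss is zero at perfect prediction and matches hand sums", {
  cfg <- tiny_cfg(alpha = 1, beta = 1, gamma = 1)
  M <- 3L; N <- 4L
  truth <- list(D_inter = matrix(stats::runif(M * N, 2, 8), M, N),
                D_lig = matrix(stats::runif(M * M, 1, 5), M, M),
                affinity = 5.5)
  perfect <- list(D_inter = aconst(matrix(as.vector(t(truth$D_inter)))),
                  D_lig = aconst(matrix(as.vector(t(truth$D_lig)))),
                  affinity = aconst(matrix(5.5)))
  expect_equal(as.numeric(aval(total_loss(perfect, truth, cfg))), 0)
  # alpha-only with every inter error = 3 A -> 2.5 from the Huber branch
  off <- perfect
  off$D_inter <- aconst(matrix(as.vector(t(truth$D_inter)) + 3))
  cfg_a <- tiny_cfg(alpha = 1, beta = 0, gamma = 0)
  expect_equal(as.numeric(aval(total_loss(off, truth, cfg_a))), 2.5)
  # random instance vs hand-summed three-term oracle
  set.seed(50)
  pred <- list(D_inter = aconst(matrix(stats::rnorm(M * N, 5, 2))),
               D_lig = aconst(matrix(stats::rnorm(M * M, 3, 2))),
               affinity = aconst(matrix(4.2)))
  cfg_w <- tiny_cfg(alpha = 0.7, beta = 0.2, gamma = 1.5)
  want <- 0.7 * mean(smooth_l1(aval(pred$D_inter), as.vector(t(truth$D_inter)))) +
    0.2 * mean(smooth_l1(aval(pred$D_lig), as.vector(t(truth$D_lig)))) +
    1.5 * smooth_l1(4.2, 5.5)
  expect_equal(as.numeric(aval(total_loss(pred, truth, cfg_w))), want,
               tolerance = 1e-12)
})

test_that("missing affinity label errors unless gamma is auto-zeroed", {
  cfg <- tiny_cfg()
  truth <- list(D_inter = matrix(1, 2, 2), D_lig = matrix(1, 2, 2),
                affinity = NULL)
  pred <- list(D_inter = aconst(matrix(1, 4, 1)),
               D_lig = aconst(matrix(1, 4, 1)),
               affinity = aconst(matrix(0)))
  expect_error(total_loss(pred, truth, cfg), "affinity label")
  cfg0 <- tiny_cfg(auto_zero_gamma = TRUE)
  expect_equal(as.numeric(aval(total_loss(pred, truth, cfg0))), 0)
})

test_that("gradient reaches every trainable parameter", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 32)
  cx <- make_synthetic_complex(M = 5, N = 7, seed = 12)
  leaves <- pairdock:::ad_collect_params(model$params)
  pairdock:::ad_reset()
  pairdock:::ad_zero_grad(leaves)
  fw <- pd_forward(model, cx$ligand, cx$pocket, 1)
  loss <- total_loss(fw$nodes, pairdock:::complex_truth(cx), cfg)
  pairdock:::ad_backward(loss)
  nz <- vapply(leaves, function(p) !is.null(p$grad) && any(p$grad != 0),
               logical(1))
  expect_true(all(nz))
  pairdock:::ad_reset()
})
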