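# Atom-pair attentive encoding block: initialization, layer oracles,
# SE(3) invariance and permutation equivariance.

ad <- function(name) get(name, envir = asNamespace("pairdock"))
aconst <- function(x) ad("ad_const")(x)
aval <- function(x) ad("ad_val")(x)

test_that("atom embedding initialization is the bare linear map", {
  W <- ad("ad_param")(diag(4))
  h <- matrix(0, 2, 4); h[2, 3] <- 1
  m <- aval(init_atom_embedding(h, list(W = W, b = NULL)))
  expect_equal(m[1, ], rep(0, 4))     # zero features -> zero embedding
  expect_equal(m[2, ], h[2, ])        # identity selector reproduces input
  # equal features -> equal embeddings
  h2 <- matrix(1, 2, 4)
  m2 <- aval(init_atom_embedding(h2, list(W = W, b = NULL)))
  expect_equal(m2[1, ], m2[2, ])
})

test_that("pair embedding initialization is rigid-transform invariant", {
  set.seed(11)
  model <- pd_model(tiny_cfg(), seed = 4)
  enc <- model$params$lig_enc
  coords <- matrix(stats::rnorm(15, sd = 2), 5, 3)
  els <- c("C", "N", "O", "C", "C")
  t1 <- aval(init_pair_embedding(coords, els, enc$gauss, enc$W_t))
  tr <- random_rigid_transform()
  t2 <- aval(init_pair_embedding(apply_rigid(coords, tr), els, enc$gauss, enc$W_t))
  expect_lt(max_rel_dev(t1, t2), 1e-6)
  expect_error(init_pair_embedding(coords * NA, els, enc$gauss, enc$W_t),
               "finite")
})

test_that("attention bias of -1e9 silences the corresponding pair", {
  logits <- matrix(c(0, -1e9, 1, 2), 2, 2, byrow = TRUE)
  w <- aval(ad("ad_softmax_rows")(aconst(logits)))
  expect_lt(w[1, 2], 1e-12)
  expect_equal(rowSums(w), c(1, 1))
})

test_that("single-atom attention reduces to the identity softmax", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 5)
  blk <- model$params$lig_enc$blocks[[1]]
  m <- ad("ad_param")(matrix(stats::rnorm(cfg$d_atom), 1))
  t <- ad("ad_param")(matrix(stats::rnorm(cfg$d_pair), 1))
  out <- atom_attention(m, t, blk$attn, cfg)
  expect_true(all(is.finite(aval(out$m))))
  # softmax over a single key must be exactly 1 -> output = value projection
  expect_equal(dim(aval(out$m)), c(1L, cfg$d_atom))
})

test_that("residual layers collapse to identity when branch output weights are zero", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 6)
  n <- 4
  tflat <- rand_pair(n, n, cfg$d_pair)
  tri <- model$params$lig_enc$blocks[[1]]$tri
  tri$out$W$value[] <- 0; tri$out$b$value[] <- 0
  expect_equal(aval(self_triangular_update(aconst(tflat), tri, n)), tflat)
  ax <- model$params$lig_enc$blocks[[1]]$axial
  ax$o$W$value[] <- 0; ax$o$b$value[] <- 0
  expect_equal(aval(pair_axial_attention(aconst(tflat), ax, n, cfg)), tflat)
})

test_that("self-triangular update matches the brute-force triple loop", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 7)
  tri <- model$params$lig_enc$blocks[[1]]$tri
  for (n in c(2L, 5L)) {
    set.seed(n)
    tflat <- rand_pair(n, n, cfg$d_pair)
    got <- aval(self_triangular_update(aconst(tflat), tri, n))
    want <- ref_self_triangular(tflat, tri, n)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("pair axial attention matches direct equation evaluation", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 8)
  ax <- model$params$lig_enc$blocks[[1]]$axial
  set.seed(9)
  n <- 4L
  tflat <- rand_pair(n, n, cfg$d_pair)
  got <- aval(pair_axial_attention(aconst(tflat), ax, n, cfg))
  want <- ref_pair_axial(tflat, ax, n, cfg$n_heads)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("axial attention weights normalize over the third index", {
  set.seed(10)
  n <- 3L; H <- 2L; dh <- 2L
  q <- rand_pair(n, n, H * dh); k <- rand_pair(n, n, H * dh)
  v <- rand_pair(n, n, H * dh); b <- rand_pair(n, n, H)
  # all-equal values: output = g-free sum_l alpha (v_il + v_lk); with v = 1
  # everywhere the aggregate must equal 2 exactly iff weights sum to 1
  ones <- matrix(1, n * n, H * dh)
  out <- aval(ad("ad_pair_axial")(aconst(q), aconst(k), aconst(ones),
                                  aconst(b), n, H))
  expect_equal(out, matrix(2, n * n, H * dh), tolerance = 1e-12)
})

test_that("encoding with zero blocks returns the initialized embeddings", {
  cfg <- tiny_cfg(n_blocks = 0L)
  model <- pd_model(cfg, seed = 12)
  cx <- make_synthetic_complex(M = 5, N = 8, seed = 3)
  enc <- encode_molecule(model$params$lig_enc, cfg,
                         feats = cx$ligand$atom_features,
                         coords = cx$ligand$conformers[[1]],
                         elements = cx$ligand$mol$elements,
                         bond_features = cx$ligand$bond_features)
  direct_m <- aval(init_atom_embedding(cx$ligand$atom_features,
                                       model$params$lig_enc$W_h))
  expect_equal(aval(enc$atoms), direct_m)
})

test_that("encoder outputs are permutation equivariant", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 13)
  cx <- make_synthetic_complex(M = 6, N = 8, seed = 21)
  lig <- cx$ligand
  M <- lig$atom_count
  enc1 <- encode_molecule(model$params$lig_enc, cfg, lig$atom_features,
                          lig$conformers[[1]], lig$mol$elements,
                          lig$bond_features)
  set.seed(1)
  perm <- sample(M)   # new index -> old index
  old_of_new <- perm
  b <- lig$mol$bonds
  new_of_old <- order(perm)
  b$i <- new_of_old[b$i]; b$k <- new_of_old[b$k]
  mol2 <- pd_mol(lig$mol$elements[old_of_new], b[, c("i", "k", "order", "aromatic")],
                 lig$mol$charges[old_of_new])
  lig2 <- ligand_record(mol2,
                        conformers = list(lig$conformers[[1]][old_of_new, ]))
  enc2 <- encode_molecule(model$params$lig_enc, cfg, lig2$atom_features,
                          lig2$conformers[[1]], lig2$mol$elements,
                          lig2$bond_features)
  expect_lt(max(abs(aval(enc2$atoms) - aval(enc1$atoms)[old_of_new, ])), 1e-8)
  pair_perm <- as.vector(vapply(seq_len(M), function(i) {
    (old_of_new[i] - 1L) * M + old_of_new
  }, integer(M)))
  expect_lt(max(abs(aval(enc2$pairs) - aval(enc1$pairs)[pair_perm, ])), 1e-8)
})

test_that("encoder is invariant to rigid transforms of the conformer", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 14)
  cx <- make_synthetic_complex(M = 6, N = 8, seed = 22)
  lig <- cx$ligand
  enc1 <- encode_molecule(model$params$lig_enc, cfg, lig$atom_features,
                          lig$conformers[[1]], lig$mol$elements,
                          lig$bond_features)
  set.seed(2)
  tr <- random_rigid_transform()
  enc2 <- encode_molecule(model$params$lig_enc, cfg, lig$atom_features,
                          apply_rigid(lig$conformers[[1]], tr),
                          lig$mol$elements, lig$bond_features)
  expect_lt(max_rel_dev(aval(enc1$pairs), aval(enc2$pairs)), 1e-5)
  expect_lt(max_rel_dev(aval(enc1$atoms), aval(enc2$atoms)), 1e-5)
})
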