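# Mutual interaction block: outer-product init, triangular/axial/
# communication oracles, permutation and rigid-motion invariance.

ad <- function(name) get(name, envir = asNamespace("pairdock"))
aconst <- function(x) ad("ad_const")(x)
aval <- function(x) ad("ad_val")(x)

test_that("complex pair init is the projected outer product", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 15)
  M <- 3L; N <- 2L; da <- cfg$d_atom
  m <- matrix(stats::rnorm(M * da), M)
  n <- matrix(stats::rnorm(N * da), N)
  z <- aval(init_complex_pair(aconst(m), aconst(n), model$params$z_init))
  # nested-loop oracle
  W <- model$params$z_init$W$value; b <- model$params$z_init$b$value
  for (i in seq_len(M)) for (j in seq_len(N)) {
    op <- as.vector(t(outer(m[i, ], n[j, ])))   # row-major (u, v) flatten
    expect_equal(z[pair_row(i, j, N), ], as.vector(op %*% W + b),
                 tolerance = 1e-10)
  }
  # bilinearity: zero atom embedding -> bias-only row
  m0 <- m; m0[2, ] <- 0
  z0 <- aval(init_complex_pair(aconst(m0), aconst(n), model$params$z_init))
  expect_equal(z0[pair_row(2, 1, N), ], as.vector(b))
  # M = N = 1 degenerate shape
  z11 <- aval(init_complex_pair(aconst(m[1, , drop = FALSE]),
                                aconst(n[1, , drop = FALSE]),
                                model$params$z_init))
  expect_equal(dim(z11), c(1L, cfg$d_pair))
})

test_that("complex triangular update matches the brute-force loops", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 16)
  ctri <- model$params$inter[[1]]$ctri
  for (dims in list(c(2L, 2L), c(3L, 5L))) {
    M <- dims[1]; N <- dims[2]
    set.seed(M * 10 + N)
    z <- rand_pair(M, N, cfg$d_pair)
    tl <- rand_pair(M, M, cfg$d_pair)
    p <- rand_pair(N, N, cfg$d_pair)
    state <- list(z = aconst(z), t = aconst(tl), p = aconst(p), M = M, N = N)
    got <- aval(complex_triangular_update(state, ctri))
    want <- ref_complex_triangular(z, tl, p, ctri, M, N)
    expect_lt(max(abs(got - want)), 1e-6)
  }
  # identity when the branch output projection is zeroed
  ctri$out$W$value[] <- 0; ctri$out$b$value[] <- 0
  M <- 3L; N <- 4L
  z <- rand_pair(M, N, cfg$d_pair)
  state <- list(z = aconst(z), t = aconst(rand_pair(M, M, cfg$d_pair)),
                p = aconst(rand_pair(N, N, cfg$d_pair)), M = M, N = N)
  expect_equal(aval(complex_triangular_update(state, ctri)), z)
})

test_that("complex-to-ligand pooled product matches the loop oracle", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 17)
  pars <- model$params$inter[[1]]
  M <- 3L; N <- 4L
  set.seed(34)
  z <- rand_pair(M, N, cfg$d_pair)
  tl <- rand_pair(M, M, cfg$d_pair)
  state <- list(z = aconst(z), t = aconst(tl), M = M, N = N)
  cfg_plain <- tiny_cfg(use_self_triangular = FALSE, use_pair_axial = FALSE)
  got <- aval(complex_to_ligand_communication(state, pars, cfg_plain))
  zn <- ref_ln(z, pars$comm$ln_z)
  tn <- ref_ln(tl, pars$comm$ln_t)
  s <- ref_comm_sum(zn, M, N)
  want <- tl + plogis(ref_lin(tn, pars$comm$g)) * ref_lin(s, pars$comm$out)
  expect_lt(max(abs(got - want)), 1e-6)
  # z = 0: the pooled sum vanishes, leaving the pure bias path
  z0 <- matrix(0, M * N, cfg$d_pair)
  state0 <- list(z = aconst(z0), t = aconst(tl), M = M, N = N)
  got0 <- aval(complex_to_ligand_communication(state0, pars, cfg_plain))
  zn0 <- ref_ln(z0, pars$comm$ln_z)   # LN of zeros is beta, not zero
  want0 <- tl + plogis(ref_lin(tn, pars$comm$g)) *
    ref_lin(ref_comm_sum(zn0, M, N), pars$comm$out)
  expect_lt(max(abs(got0 - want0)), 1e-6)
})

test_that("row attention of the complex axial layer matches a per-row MHA oracle", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 18)
  pars <- model$params$inter[[1]]$crow
  M <- 3L; N <- 5L
  set.seed(35)
  z <- rand_pair(M, N, cfg$d_pair)
  zn <- ref_ln(z, pars$ln)
  q <- ref_lin(zn, pars$q); k <- ref_lin(zn, pars$k); v <- ref_lin(zn, pars$v)
  want_att <- matrix(0, M * N, cfg$d_pair)
  for (i in seq_len(M)) {
    rows <- ((i - 1) * N + 1):(i * N)
    want_att[rows, ] <- ref_block_mha_one(q[rows, , drop = FALSE],
                                          k[rows, , drop = FALSE],
                                          v[rows, , drop = FALSE], cfg$n_heads)
  }
  want <- plogis(ref_lin(zn, pars$gate)) * want_att
  want <- ref_lin(want, pars$o)
  got <- aval(pairdock:::caxial_branch(aconst(z), pars, M, cfg$n_heads))
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("attention over a single pocket atom gives weight one", {
  q <- matrix(stats::rnorm(4), 1); k <- matrix(stats::rnorm(4), 1)
  v <- matrix(stats::rnorm(4), 1)
  out <- aval(ad("ad_block_mha")(aconst(q), aconst(k), aconst(v),
                                 nblocks = 1L, H = 2L))
  expect_equal(out, v)   # softmax over one key is identically 1
})

test_that("one interaction iteration equals the manual layer composition", {
  cfg <- tiny_cfg(n_iter = 1L)
  model <- pd_model(cfg, seed = 19)
  cx <- make_synthetic_complex(M = 5, N = 7, seed = 8)
  enc_l <- encode_molecule(model$params$lig_enc, cfg, cx$ligand$atom_features,
                           cx$ligand$conformers[[1]], cx$ligand$mol$elements,
                           cx$ligand$bond_features)
  enc_p <- encode_molecule(model$params$poc_enc, cfg, cx$pocket$atom_features,
                           cx$pocket$coords, cx$pocket$elements)
  z0 <- init_complex_pair(enc_l$atoms, enc_p$atoms, model$params$z_init)
  st <- list(z = z0, t = enc_l$pairs, p = enc_p$pairs, M = 5L, N = 7L)
  auto <- mutual_interaction(st, model$params$inter, cfg)
  pars <- model$params$inter[[1]]
  st$z <- complex_triangular_update(st, pars$ctri)
  st$z <- complex_axial_attention(st, pars, cfg)
  st$t <- complex_to_ligand_communication(st, pars, cfg)
  expect_equal(aval(auto$z), aval(st$z))
  expect_equal(aval(auto$t), aval(st$t))
})

test_that("pocket atom permutation permutes complex columns consistently", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 23)
  cx <- make_synthetic_complex(M = 5, N = 6, seed = 9)
  fw1 <- pd_forward(model, cx$ligand, cx$pocket, 1)
  set.seed(3)
  perm <- sample(cx$pocket$atom_count)
  poc2 <- pocket_record(cx$pocket$elements[perm],
                        cx$pocket$coords[perm, ],
                        cx$pocket$residue_ids[perm])
  fw2 <- pd_forward(model, cx$ligand, poc2, 1)
  expect_lt(max(abs(fw2$D_inter - fw1$D_inter[, perm])), 1e-8)
  expect_lt(max(abs(fw2$D_lig - fw1$D_lig)), 1e-8)
  expect_lt(abs(fw2$affinity - fw1$affinity), 1e-8)
})

test_that("the full network is invariant to joint rigid transforms", {
  cfg <- tiny_cfg()
  model <- pd_model(cfg, seed = 24)
  cx <- make_synthetic_complex(M = 6, N = 9, seed = 10)
  fw1 <- pd_forward(model, cx$ligand, cx$pocket, 1)
  set.seed(4)
  cx2 <- transform_complex(cx, random_rigid_transform())
  fw2 <- pd_forward(model, cx2$ligand, cx2$pocket, 1)
  expect_lt(max_rel_dev(fw1$D_inter, fw2$D_inter), 1e-5)
  expect_lt(max_rel_dev(fw1$D_lig, fw2$D_lig), 1e-5)
  expect_lt(abs(fw1$affinity - fw2$affinity), 1e-6)
})
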