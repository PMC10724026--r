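# Independent reference implementations (plain loops, no autodiff) used as
# oracles against the vectorized layers, plus small shared fixtures.

ref_ln <- function(X, p, eps = 1e-5) {
  g <- p$g$value; b <- p$b$value
  t(apply(X, 1L, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * g + b
  }))
}

ref_lin <- function(X, p) {
  out <- X %*% p$W$value
  if (!is.null(p$b)) out <- out + rep(p$b$value, each = nrow(out))
  out
}

ref_glu <- function(X, p) {
  plogis(ref_lin(X, p$gate)) * ref_lin(X, p$val)
}

# Self-triangular update (outgoing + incoming edges in one update),
# triple loop over (i, k, l); l ranges over all atoms.
ref_self_triangular <- function(tflat, pars, n) {
  tn <- ref_ln(tflat, pars$ln)
  a <- ref_glu(tn, pars$a)
  b <- ref_glu(tn, pars$b)
  g <- plogis(ref_lin(tn, pars$g))
  s <- matrix(0, n * n, ncol(tflat))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0
    for (l in seq_len(n)) {
      acc <- acc + a[pair_row(i, l, n), ] * b[pair_row(k, l, n), ] +
        a[pair_row(l, i, n), ] * b[pair_row(l, k, n), ]
    }
    s[pair_row(i, k, n), ] <- acc
  }
  tflat + g * ref_lin(s, pars$out)
}

# Pair axial attention: direct evaluation of the fused-softmax equations.
ref_pair_axial <- function(tflat, pars, n, H) {
  tn <- ref_ln(tflat, pars$ln)
  q <- ref_lin(tn, pars$q); k <- ref_lin(tn, pars$k); v <- ref_lin(tn, pars$v)
  bias <- tn %*% pars$bias$W$value
  gate <- plogis(ref_lin(tn, pars$gate))
  dh <- ncol(q) / H
  o <- matrix(0, n * n, ncol(q))
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Bm <- matrix(0, n, n)
    for (i in seq_len(n)) for (kk in seq_len(n)) {
      Bm[i, kk] <- bias[pair_row(i, kk, n), h]
    }
    for (i in seq_len(n)) for (kk in seq_len(n)) {
      e <- numeric(n)
      for (l in seq_len(n)) {
        e[l] <- sum(q[pair_row(i, kk, n), cols] *
                      (k[pair_row(i, l, n), cols] +
                         k[pair_row(l, kk, n), cols])) / sqrt(dh) +
          Bm[kk, l] + Bm[l, i]
      }
      al <- exp(e - max(e)); al <- al / sum(al)
      acc <- 0
      for (l in seq_len(n)) {
        acc <- acc + al[l] * (v[pair_row(i, l, n), cols] +
                                v[pair_row(l, kk, n), cols])
      }
      o[pair_row(i, kk, n), cols] <- gate[pair_row(i, kk, n), cols] * acc
    }
  }
  tflat + ref_lin(o, pars$o)
}

# Complex triangular update, triple loop.
ref_complex_triangular <- function(zflat, tflat, pflat, pars, M, N) {
  zn <- ref_ln(zflat, pars$ln_z)
  tn <- ref_ln(tflat, pars$ln_t)
  pn <- ref_ln(pflat, pars$ln_p)
  a <- ref_glu(zn, pars$a); b <- ref_glu(zn, pars$b)
  tg <- ref_glu(tn, pars$tg); pg <- ref_glu(pn, pars$pg)
  g <- plogis(ref_lin(zn, pars$g))
  s <- matrix(0, M * N, ncol(zflat))
  for (i in seq_len(M)) for (j in seq_len(N)) {
    acc <- 0
    for (k in seq_len(M)) {
      acc <- acc + tg[pair_row(i, k, M), ] * a[pair_row(k, j, N), ]
    }
    for (kp in seq_len(N)) {
      acc <- acc + b[pair_row(i, kp, N), ] * pg[pair_row(kp, j, N), ]
    }
    s[pair_row(i, j, N), ] <- acc
  }
  zflat + g * ref_lin(s, pars$out)
}

# Complex-to-ligand pooled product (Eq-22 inner sum only).
ref_comm_sum <- function(znflat, M, N) {
  s <- matrix(0, M * M, ncol(znflat))
  for (i in seq_len(M)) for (k in seq_len(M)) {
    acc <- 0
    for (j in seq_len(N)) {
      acc <- acc + znflat[pair_row(i, j, N), ] * znflat[pair_row(k, j, N), ]
    }
    s[pair_row(i, k, M), ] <- acc
  }
  s
}

# Affinity head: per-pair gated projection, explicit-loop mean, final linear.
ref_affinity <- function(zflat, m, n, pars, M, N) {
  zn <- ref_ln(zflat, pars$ln_z)
  mi <- ref_ln(m, pars$ln_m)
  nj <- ref_ln(n, pars$ln_n)
  acc <- 0
  for (i in seq_len(M)) for (j in seq_len(N)) {
    aij <- ref_glu(rbind(c(zn[pair_row(i, j, N), ], mi[i, ], nj[j, ])),
                   pars$aff_glu)
    acc <- acc + aij
  }
  as.numeric(ref_lin(acc / (M * N), pars$aff_out))
}

# Standard per-row multi-head attention oracle for one block of rows.
ref_block_mha_one <- function(Q, K, V, H) {
  dh <- ncol(Q) / H
  out <- matrix(0, nrow(Q), ncol(Q))
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    A <- t(apply(S, 1L, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    if (nrow(S) == 1L) A <- matrix(A, 1L)
    out[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out
}

# ---- shared fixtures --------------------------------------------------------

tiny_cfg <- function(...) {
  args <- list(d_atom = 32L, d_pair = 16L, n_gauss = 8L, n_heads = 4L,
               n_blocks = 2L, n_iter = 2L)
  do.call(pd_config, utils::modifyList(args, list(...)))
}

random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, sd = 8))
}

apply_rigid <- function(x, tr) x %*% tr$R + rep(tr$t, each = nrow(x))

transform_complex <- function(cx, tr) {
  cx$ligand$conformers <- lapply(cx$ligand$conformers, apply_rigid, tr = tr)
  if (!is.null(cx$ligand$holo_coords)) {
    cx$ligand$holo_coords <- apply_rigid(cx$ligand$holo_coords, tr)
  }
  cx$pocket$coords <- apply_rigid(cx$pocket$coords, tr)
  cx
}

rand_pair <- function(n1, n2, d) matrix(stats::rnorm(n1 * n2 * d), n1 * n2, d)

max_rel_dev <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)))
}
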