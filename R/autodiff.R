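# Lightweight reverse-mode automatic differentiation on dense matrices.
#
# A global tape records operation nodes in execution order; ad_backward()
# replays it in reverse, accumulating gradients into node$grad. Leaves
# (parameters, constants) live off the tape and persist across tapes, so a
# training loop resets the tape each step while parameter environments survive.
# Values are plain numeric matrices; pair tensors are stored flattened
# row-major, i.e. row (i-1)*ncol + k holds pair (i, k).

.ad <- new.env(parent = emptyenv())
.ad$nodes <- vector("list", 512L)
.ad$n <- 0L

#' Reset the autodiff tape
#'
#' Discards all recorded operation nodes. Parameter leaves are unaffected
#' (their accumulated gradients are cleared separately by [ad_zero_grad()]).
#' @return Invisibly `NULL`.
#' @keywords internal
ad_reset <- function() {
  .ad$nodes <- vector("list", 512L)
  .ad$n <- 0L
  invisible(NULL)
}

is_adnode <- function(x) inherits(x, "adnode")

#' Value of a node or plain numeric
#' @param x An `adnode` or numeric array.
#' @return The underlying numeric value.
#' @keywords internal
ad_val <- function(x) if (is_adnode(x)) x$value else x

adnode <- function(value, backfun = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfun <- backfun
  class(nd) <- "adnode"
  if (!is.null(backfun)) {
    n <- .ad$n + 1L
    if (n > length(.ad$nodes)) length(.ad$nodes) <- 2L * n
    .ad$nodes[[n]] <- nd
    .ad$n <- n
  }
  nd
}

#' Create a trainable parameter leaf
#' @param value Numeric matrix or vector (kept as given).
#' @return An `adnode` leaf; gradients accumulate in `$grad`.
#' @keywords internal
ad_param <- function(value) adnode(value)

#' Create a constant leaf (no gradient tracked)
#' @keywords internal
ad_const <- function(value) {
  nd <- adnode(value)
  nd$constant <- TRUE
  nd
}

ad_accum <- function(x, g) {
  if (is_adnode(x) && is.null(x$constant)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

#' Run the backward pass from a scalar loss node
#' @param loss An `adnode` holding a length-1 value.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss), length(loss$value) == 1L)
  loss$grad <- array(1, dim = dim(as.matrix(loss$value)))
  if (.ad$n > 0L) {
    for (i in seq.int(.ad$n, 1L)) {
      nd <- .ad$nodes[[i]]
      if (!is.null(nd$grad)) nd$backfun(nd$grad)
    }
  }
  invisible(NULL)
}

#' Collect all parameter leaves from a nested list
#' @param x Nested list containing `adnode` leaves.
#' @return Flat (unnamed) list of `adnode`s.
#' @keywords internal
ad_collect_params <- function(x) {
  if (is_adnode(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, ad_collect_params)))
  list()
}

#' Clear gradients on a (nested) list of parameter leaves
#' @param params List of `adnode` leaves (possibly nested).
#' @keywords internal
ad_zero_grad <- function(params) {
  for (p in ad_collect_params(params)) p$grad <- NULL
  invisible(NULL)
}

# ---- basic ops --------------------------------------------------------------

ad_add <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  adnode(va + vb, function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

ad_sub <- function(a, b) {
  adnode(ad_val(a) - ad_val(b), function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  })
}

ad_mul <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  adnode(va * vb, function(g) {
    ad_accum(a, g * vb)
    ad_accum(b, g * va)
  })
}

ad_scale <- function(a, s) {
  adnode(ad_val(a) * s, function(g) ad_accum(a, g * s))
}

ad_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  A <- ad_val(a); B <- ad_val(b)
  Av <- if (ta) t(A) else A
  Bv <- if (tb) t(B) else B
  adnode(Av %*% Bv, function(g) {
    if (is_adnode(a)) {
      da <- tcrossprod(g, Bv)
      ad_accum(a, if (ta) t(da) else da)
    }
    if (is_adnode(b)) {
      db <- crossprod(Av, g)
      ad_accum(b, if (tb) t(db) else db)
    }
  })
}

# x: n x d, W: d x k, b: length-k numeric vector (or NULL)
ad_linear <- function(x, W, b = NULL) {
  X <- ad_val(x); Wv <- ad_val(W)
  val <- X %*% Wv
  if (!is.null(b)) val <- val + rep(ad_val(b), each = nrow(val))
  adnode(val, function(g) {
    ad_accum(x, tcrossprod(g, Wv))
    ad_accum(W, crossprod(X, g))
    if (!is.null(b)) ad_accum(b, colSums(g))
  })
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ad_val(x)))
  adnode(s, function(g) ad_accum(x, g * s * (1 - s)))
}

ad_gelu <- function(x) {
  v <- ad_val(x)
  p <- stats::pnorm(v)
  adnode(v * p, function(g) ad_accum(x, g * (p + v * stats::dnorm(v))))
}

ad_softmax_rows <- function(x) {
  v <- ad_val(x)
  e <- exp(v - apply(v, 1L, max))
  p <- e / rowSums(e)
  adnode(p, function(g) {
    ad_accum(x, p * (g - rowSums(g * p)))
  })
}

# Row-wise layer normalization. gamma, beta: length-d numeric parameter leaves.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- ad_val(x)
  d <- ncol(v); n <- nrow(v)
  mu <- rowMeans(v)
  xc <- v - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  gm <- ad_val(gamma); bt <- ad_val(beta)
  val <- xhat * rep(gm, each = n) + rep(bt, each = n)
  adnode(val, function(g) {
    dxhat <- g * rep(gm, each = n)
    ad_accum(gamma, colSums(g * xhat))
    ad_accum(beta, colSums(g))
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    ad_accum(x, (inv / d) * (d * dxhat - s1 - xhat * s2))
  })
}

ad_concat_cols <- function(xs) {
  vals <- lapply(xs, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  val <- do.call(cbind, vals)
  ends <- cumsum(widths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  adnode(val, function(g) {
    for (i in seq_along(xs)) {
      ad_accum(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_slice_cols <- function(x, idx) {
  v <- ad_val(x)
  adnode(v[, idx, drop = FALSE], function(g) {
    gx <- matrix(0, nrow(v), ncol(v))
    gx[, idx] <- g
    ad_accum(x, gx)
  })
}

# Gather rows: out[r, ] = x[idx[r], ]. Backward scatter-adds duplicated rows.
ad_gather_rows <- function(x, idx) {
  v <- ad_val(x)
  adnode(v[idx, , drop = FALSE], function(g) {
    agg <- rowsum(g, group = idx)            # sorted unique groups as rownames
    full <- matrix(0, nrow(v), ncol(v))
    full[as.integer(rownames(agg)), ] <- agg
    ad_accum(x, full)
  })
}

# Row permutation: out[r, ] = x[perm[r], ] with perm a bijection.
ad_permute_rows <- function(x, perm) {
  v <- ad_val(x)
  ip <- integer(length(perm))
  ip[perm] <- seq_along(perm)
  adnode(v[perm, , drop = FALSE], function(g) ad_accum(x, g[ip, , drop = FALSE]))
}

ad_mean_all <- function(x) {
  v <- ad_val(x)
  adnode(matrix(mean(v), 1L, 1L), function(g) {
    ad_accum(x, array(as.numeric(g) / length(v), dim = dim(v)))
  })
}

ad_colmeans <- function(x) {
  v <- ad_val(x)
  n <- nrow(v)
  adnode(matrix(colMeans(v), 1L, ncol(v)), function(g) {
    ad_accum(x, matrix(rep(as.numeric(g) / n, each = n), n, ncol(v)))
  })
}

# Smooth-L1 (Huber, delta = 1) between a predicted node and a fixed numeric
# target, averaged over all elements: 0.5 r^2 for |r| < 1, |r| - 0.5 otherwise.
ad_smooth_l1_mean <- function(pred, target) {
  v <- ad_val(pred)
  r <- v - target
  a <- abs(r)
  val <- mean(ifelse(a < 1, 0.5 * r * r, a - 0.5))
  adnode(matrix(val, 1L, 1L), function(g) {
    dr <- ifelse(a < 1, r, sign(r)) / length(r)
    ad_accum(pred, array(as.numeric(g) * dr, dim = dim(v)))
  })
}

# ---- fused pair-tensor ops --------------------------------------------------

# Row permutation that transposes a flattened nr x nc pair grid:
# column-major readout of the row-major index grid.
chan_tperm <- function(nr, nc) as.vector(matrix(seq_len(nr * nc), nr, nc,
                                                byrow = TRUE))

# Core per-channel contraction: A ((I*K) x C row-major), B ((K*J) x C)
# -> out[(i-1)*J + j, c] = sum_k A[(i-1)*K + k, c] * B[(k-1)*J + j, c].
# Vectorized over everything but the contraction index.
chan_core <- function(A, B, I, K, J) {
  C <- ncol(A)
  out <- matrix(0, I * J, C)
  ii <- rep(seq_len(I), each = J)
  jj <- rep(seq_len(J), times = I)
  arows <- (seq_len(I) - 1L) * K
  for (k in seq_len(K)) {
    Ak <- A[arows + k, , drop = FALSE]          # I x C
    Bk <- B[((k - 1L) * J + 1L):(k * J), , drop = FALSE]  # J x C
    out <- out + Ak[ii, , drop = FALSE] * Bk[jj, , drop = FALSE]
  }
  out
}

# Per-channel matrix product of two flattened pair tensors.
# x: (nrx*ncx) x C row-major, y: (nry*ncy) x C row-major; per channel c,
# Z_c = op(X_c) %*% op(Y_c) with optional transposes; returned flattened
# row-major, same channel count.
ad_chan_matmul <- function(x, y, nrx, ncx, nry, ncy, ta = FALSE, tb = FALSE) {
  X <- ad_val(x); Y <- ad_val(y)
  C <- ncol(X)
  stopifnot(ncol(Y) == C, nrow(X) == nrx * ncx, nrow(Y) == nry * ncy)
  ar <- if (ta) ncx else nrx; ac <- if (ta) nrx else ncx
  br <- if (tb) ncy else nry; bc <- if (tb) nry else ncy
  stopifnot(ac == br)
  A <- if (ta) X[chan_tperm(nrx, ncx), , drop = FALSE] else X
  B <- if (tb) Y[chan_tperm(nry, ncy), , drop = FALSE] else Y
  adnode(chan_core(A, B, ar, ac, bc), function(g) {
    if (is_adnode(x)) {
      # dA[(i,k)] = sum_j G[(i,j)] B[(k,j)]
      dA <- chan_core(g, B[chan_tperm(ac, bc), , drop = FALSE], ar, bc, ac)
      ad_accum(x, if (ta) dA[chan_tperm(ar, ac), , drop = FALSE] else dA)
    }
    if (is_adnode(y)) {
      # dB[(k,j)] = sum_i A[(i,k)] G[(i,j)]
      dB <- chan_core(A[chan_tperm(ar, ac), , drop = FALSE], g, ac, ar, bc)
      ad_accum(y, if (tb) dB[chan_tperm(ac, bc), , drop = FALSE] else dB)
    }
  })
}

# Row-wise outer product: m (M x da), n (N x db) ->
# out[(i-1)*N + j, (u-1)*db + v] = m[i,u] * n[j,v].
ad_outer_rows <- function(m, n) {
  Mv <- ad_val(m); Nv <- ad_val(n)
  M <- nrow(Mv); N <- nrow(Nv); da <- ncol(Mv); db <- ncol(Nv)
  iu <- rep(seq_len(M), each = N)
  jv <- rep(seq_len(N), times = M)
  cu <- rep(seq_len(da), each = db)
  cv <- rep(seq_len(db), times = da)
  rows_m <- Mv[iu, cu, drop = FALSE]
  rows_n <- Nv[jv, cv, drop = FALSE]
  adnode(rows_m * rows_n, function(g) {
    if (is_adnode(m)) {
      Tm <- g * rows_n                       # (MN) x (da*db)
      colm <- rowsum(t(Tm), group = cu)      # da x (MN), sums over v
      dm <- rowsum(t(colm), group = iu)      # M x da, sums over j
      ad_accum(m, dm)
    }
    if (is_adnode(n)) {
      Tn <- g * rows_m
      coln <- rowsum(t(Tn), group = cv)      # db x (MN)
      dn <- rowsum(t(coln), group = jv)      # N x db
      ad_accum(n, dn)
    }
  })
}

# Extract column `col` of a flattened pair tensor as an nr x nc matrix.
ad_col_as_mat <- function(x, col, nr, nc) {
  v <- ad_val(x)
  adnode(matrix(v[, col], nr, nc, byrow = TRUE), function(g) {
    gx <- matrix(0, nrow(v), ncol(v))
    gx[, col] <- as.vector(t(g))
    ad_accum(x, gx)
  })
}

# Stack matrices (all nr x nc) as the columns of a flattened pair tensor.
ad_mats_as_cols <- function(mats, nr, nc) {
  vals <- lapply(mats, ad_val)
  val <- vapply(vals, function(m) as.vector(t(m)), numeric(nr * nc))
  adnode(val, function(g) {
    for (h in seq_along(mats)) {
      ad_accum(mats[[h]], matrix(g[, h], nr, nc, byrow = TRUE))
    }
  })
}

# Multi-head attention applied independently within contiguous row blocks.
# q, k, v: (nblocks * B) x (H * dh); softmax over the B keys of each block.
ad_block_mha <- function(q, k, v, nblocks, H) {
  Q <- ad_val(q); K <- ad_val(k); V <- ad_val(v)
  P <- nrow(Q)
  stopifnot(P %% nblocks == 0L, ncol(Q) %% H == 0L)
  B <- P %/% nblocks
  dh <- ncol(Q) %/% H
  sc <- 1 / sqrt(dh)
  val <- matrix(0, P, ncol(Q))
  attn <- vector("list", nblocks * H)
  for (b in seq_len(nblocks)) {
    rows <- ((b - 1L) * B + 1L):(b * B)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * sc
      E <- exp(S - apply(S, 1L, max))
      A <- E / rowSums(E)
      attn[[(b - 1L) * H + h]] <- A
      val[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
  }
  adnode(val, function(g) {
    gq <- matrix(0, P, ncol(Q)); gk <- gq; gv <- gq
    for (b in seq_len(nblocks)) {
      rows <- ((b - 1L) * B + 1L):(b * B)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- attn[[(b - 1L) * H + h]]
        G <- g[rows, cols, drop = FALSE]
        Vb <- V[rows, cols, drop = FALSE]
        dA <- tcrossprod(G, Vb)
        gv[rows, cols] <- crossprod(A, G)
        dS <- A * (dA - rowSums(dA * A))
        gq[rows, cols] <- (dS %*% K[rows, cols, drop = FALSE]) * sc
        gk[rows, cols] <- crossprod(dS, Q[rows, cols, drop = FALSE]) * sc
      }
    }
    ad_accum(q, gq); ad_accum(k, gk); ad_accum(v, gv)
  })
}

# Axial attention over a square pair tensor (flattened M*M row-major).
# For each pair (i,k) and head h, logits over the third index l are
#   sc * sum_d Q[ik,d] (K[il,d] + K[lk,d]) + B[k,l] + B[l,i]
# and the output is sum_l alpha[ik,l] (V[il,] + V[lk,]).
# q, k, v: (M*M) x (H*dh); bias: (M*M) x H (one scalar per pair per head).
ad_pair_axial <- function(q, k, v, bias, M, H) {
  Q <- ad_val(q); K <- ad_val(k); V <- ad_val(v); Bm <- ad_val(bias)
  P <- M * M
  dh <- ncol(Q) %/% H
  sc <- 1 / sqrt(dh)
  kidx <- rep(seq_len(M), times = M)  # k of row (i-1)*M + k
  iidx <- rep(seq_len(M), each = M)   # i of row (i-1)*M + k
  iblock <- function(i) ((i - 1L) * M + 1L):(i * M)     # rows (i, .)
  kblock <- function(kk) seq.int(kk, P, by = M)          # rows (., kk)
  val <- matrix(0, P, ncol(Q))
  cache <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- Q[, cols, drop = FALSE]; Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    Bh <- matrix(Bm[, h], M, M, byrow = TRUE)            # Bh[i,k]
    E <- matrix(0, P, M)
    for (i in seq_len(M)) {
      r <- iblock(i)
      E[r, ] <- E[r, ] + sc * tcrossprod(Qh[r, , drop = FALSE], Kh[r, , drop = FALSE])
    }
    for (kk in seq_len(M)) {
      r <- kblock(kk)
      E[r, ] <- E[r, ] + sc * tcrossprod(Qh[r, , drop = FALSE], Kh[r, , drop = FALSE])
    }
    E <- E + Bh[kidx, , drop = FALSE] + t(Bh)[iidx, , drop = FALSE]
    Ex <- exp(E - apply(E, 1L, max))
    A <- Ex / rowSums(Ex)                                 # alpha[(ik), l]
    out <- matrix(0, P, dh)
    for (i in seq_len(M)) {
      r <- iblock(i)
      out[r, ] <- out[r, ] + A[r, , drop = FALSE] %*% Vh[r, , drop = FALSE]
    }
    for (kk in seq_len(M)) {
      r <- kblock(kk)
      out[r, ] <- out[r, ] + A[r, , drop = FALSE] %*% Vh[r, , drop = FALSE]
    }
    val[, cols] <- out
    cache[[h]] <- A
  }
  adnode(val, function(g) {
    gq <- matrix(0, P, ncol(Q)); gk <- gq; gv <- gq
    gb <- matrix(0, P, H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- Q[, cols, drop = FALSE]; Kh <- K[, cols, drop = FALSE]
      Vh <- V[, cols, drop = FALSE]
      A <- cache[[h]]
      G <- g[, cols, drop = FALSE]
      dA <- matrix(0, P, M)
      for (i in seq_len(M)) {
        r <- iblock(i)
        dA[r, ] <- dA[r, ] + tcrossprod(G[r, , drop = FALSE], Vh[r, , drop = FALSE])
        gv[r, cols] <- gv[r, cols] + crossprod(A[r, , drop = FALSE], G[r, , drop = FALSE])
      }
      for (kk in seq_len(M)) {
        r <- kblock(kk)
        dA[r, ] <- dA[r, ] + tcrossprod(G[r, , drop = FALSE], Vh[r, , drop = FALSE])
        gv[r, cols] <- gv[r, cols] + crossprod(A[r, , drop = FALSE], G[r, , drop = FALSE])
      }
      dE <- A * (dA - rowSums(dA * A))
      for (i in seq_len(M)) {
        r <- iblock(i)
        gq[r, cols] <- gq[r, cols] + sc * (dE[r, , drop = FALSE] %*% Kh[r, , drop = FALSE])
        gk[r, cols] <- gk[r, cols] + sc * crossprod(dE[r, , drop = FALSE], Qh[r, , drop = FALSE])
      }
      for (kk in seq_len(M)) {
        r <- kblock(kk)
        gq[r, cols] <- gq[r, cols] + sc * (dE[r, , drop = FALSE] %*% Kh[r, , drop = FALSE])
        gk[r, cols] <- gk[r, cols] + sc * crossprod(dE[r, , drop = FALSE], Qh[r, , drop = FALSE])
      }
      # bias grads: dB[k,l] += sum_i dE[(ik),l]; dB[l,i] += sum_k dE[(ik),l]
      S1 <- rowsum(dE, group = kidx)   # M(k) x M(l)
      S2 <- rowsum(dE, group = iidx)   # M(i) x M(l)
      dBh <- S1 + t(S2)
      gb[, h] <- as.vector(t(dBh))
    }
    ad_accum(q, gq); ad_accum(k, gk); ad_accum(v, gv); ad_accum(bias, gb)
  })
}

# Pair-type aware Gaussian distance basis (learnable affine + Gaussian bank).
# d: length-P numeric distances (constant); ptype: length-P integer pair types;
# a, b: per-type affine parameter leaves; mu, sigma: length-Hg parameter leaves.
# Returns P x Hg node with entries dnorm(a[pt]*d + b[pt], mu[h], sigma[h]);
# sigma is clamped below at 1e-5.
ad_gauss_basis <- function(d, ptype, a, b, mu, sigma) {
  av <- ad_val(a); bv <- ad_val(b)
  muv <- ad_val(mu); sgv <- pmax(ad_val(sigma), 1e-5)
  clamped <- ad_val(sigma) < 1e-5
  P <- length(d); Hg <- length(muv)
  x <- av[ptype] * d + bv[ptype]                  # length P
  X <- matrix(x, P, Hg)
  MU <- matrix(muv, P, Hg, byrow = TRUE)
  SG <- matrix(sgv, P, Hg, byrow = TRUE)
  Z <- (X - MU) / SG
  G <- exp(-0.5 * Z * Z) / (sqrt(2 * pi) * SG)
  scatter_by_type <- function(vals, n_types) {
    out <- numeric(n_types)
    agg <- rowsum(vals, group = ptype)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  adnode(G, function(g) {
    dGdx <- -G * Z / SG                            # d/dx of dnorm(x; mu, sg)
    gx <- rowSums(g * dGdx)                        # length P
    ad_accum(a, scatter_by_type(gx * d, length(av)))
    ad_accum(b, scatter_by_type(gx, length(bv)))
    ad_accum(mu, colSums(g * (G * Z / SG)))
    gsg <- colSums(g * G * (Z * Z - 1) / SG)
    gsg[clamped] <- 0
    ad_accum(sigma, gsg)
  })
}

# ---- numerical gradient checking -------------------------------------------

#' Finite-difference gradient check of a tape computation
#'
#' `fn` must rebuild the computation from scratch (it is called repeatedly
#' with perturbed parameter values) and return a scalar `adnode`.
#'
#' @param fn Function taking a list of numeric arrays, returning a scalar node.
#' @param params Named list of numeric arrays at which to check.
#' @param eps Finite-difference step.
#' @return Named list with, per parameter, the maximum absolute difference
#'   between analytic and numeric gradient.
#' @keywords internal
ad_gradcheck <- function(fn, params, eps = 1e-5) {
  leaves <- lapply(params, ad_param)
  ad_reset()
  loss <- fn(leaves)
  ad_backward(loss)
  out <- list()
  for (nm in names(params)) {
    v <- params[[nm]]
    ana <- leaves[[nm]]$grad
    if (is.null(ana)) ana <- array(0, dim = if (is.null(dim(v))) length(v) else dim(v))
    num <- array(0, dim = if (is.null(dim(v))) length(v) else dim(v))
    for (j in seq_along(v)) {
      vp <- v; vp[j] <- vp[j] + eps
      vm <- v; vm[j] <- vm[j] - eps
      lp <- local({
        l2 <- lapply(params, ad_param); l2[[nm]]$value <- vp
        ad_reset(); as.numeric(ad_val(fn(l2)))
      })
      lm <- local({
        l2 <- lapply(params, ad_param); l2[[nm]]$value <- vm
        ad_reset(); as.numeric(ad_val(fn(l2)))
      })
      num[j] <- (lp - lm) / (2 * eps)
    }
    out[[nm]] <- max(abs(as.numeric(ana) - as.numeric(num)))
  }
  ad_reset()
  out
}
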