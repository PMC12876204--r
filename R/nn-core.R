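# Low-level neural network primitives with explicit forward/backward
# passes.
#
# A batch of B windows of T timesteps and C features is held as a
# (B*T) x C matrix whose rows are sample-major (rows 1..T belong to sample
# 1, and so on), or equivalently as a (T, C, B) cube when a per-sample view
# is needed (attention).  All backward passes are hand-derived and are
# checked against central-difference numerical gradients in the test
# suite.

mat2cube <- function(M, T_, B) {
  aperm(array(M, c(T_, B, ncol(M))), c(1L, 3L, 2L))
}

cube2mat <- function(cb) {
  d <- dim(cb)
  p <- aperm(cb, c(1L, 3L, 2L))
  dim(p) <- c(d[1L] * d[3L], d[2L])
  p
}

# ---- elementwise -----------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- column broadcasts -----------------------------------------------------

# Expand a per-column vector to the full matrix layout (column-major), the
# fast replacement for sweep() in the hot path.
repcols <- function(v, n) rep(v, rep.int(n, length(v)))

# ---- linear ----------------------------------------------------------------

linear_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + repcols(b, nrow(Y))
  Y
}

linear_bwd <- function(X, W, dY) {
  list(
    dX = dY %*% t(W),
    dW = crossprod(X, dY),
    db = colSums(dY)
  )
}

# ---- layer normalization (row-wise) ----------------------------------------

LN_EPS <- 1e-5

layernorm_fwd <- function(X, gamma, beta) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  ivar <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * ivar
  n <- nrow(X)
  Y <- xhat * repcols(gamma, n) + repcols(beta, n)
  list(y = Y, xhat = xhat, ivar = ivar)
}

layernorm_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- dY * repcols(gamma, nrow(dY))
  dX <- cache$ivar *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

# ---- batch normalization (per column over batch x time) --------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

batchnorm_fwd <- function(X, gamma, beta, run_mean, run_var, training) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
    run_mean <- (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu
    run_var <- (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  n <- nrow(X)
  xhat <- (X - repcols(mu, n)) * repcols(ivar, n)
  Y <- xhat * repcols(gamma, n) + repcols(beta, n)
  list(
    y = Y, xhat = xhat, ivar = ivar, training = training,
    run_mean = run_mean, run_var = run_var
  )
}

batchnorm_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  n <- nrow(dY)
  dxhat <- dY * repcols(gamma, n)
  if (cache$training) {
    dX <- (dxhat - repcols(colMeans(dxhat), n) -
      xhat * repcols(colMeans(dxhat * xhat), n)) * repcols(cache$ivar, n)
  } else {
    dX <- dxhat * repcols(cache$ivar, n)
  }
  list(dX = dX, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

# ---- temporal shifts (same-padded convolution building block) --------------

# Row-shift a sample-major (B*T) x C matrix by `o` timesteps within each
# sample block, zero-filling rows that cross a block boundary.  The adjoint
# of shift by o is shift by -o.
shift_rows <- function(X, o, T_, B) {
  if (o == 0L) {
    return(X)
  }
  n <- T_ * B
  r <- seq_len(n)
  tpos <- ((r - 1L) %% T_) + 1L + o
  idx <- ifelse(tpos >= 1L & tpos <= T_, r + o, n + 1L)
  rbind(X, 0)[idx, , drop = FALSE]
}

# Grouped same-padded 1-D convolution over time, expressed as a sum of
# shifted matrix products with block-diagonal (group-masked) weights.
group_mask <- function(C, groups) {
  gid <- ceiling(seq_len(C) / (C / groups))
  outer(gid, gid, "==") * 1
}

gconv_fwd <- function(X, Wlist, b, T_, B, shifts) {
  pre <- matrix(repcols(b, nrow(X)), nrow(X), ncol(X))
  for (i in seq_along(shifts$offsets)) {
    pre <- pre + shifts$X[[i]] %*% Wlist[[i]]
  }
  pre
}

gconv_bwd <- function(dpre, Wlist, mask, T_, B, shifts) {
  dX <- matrix(0, nrow(dpre), ncol(Wlist[[1L]]))
  dW <- vector("list", length(shifts$offsets))
  for (i in seq_along(shifts$offsets)) {
    o <- shifts$offsets[i]
    dW[[i]] <- crossprod(shifts$X[[i]], dpre) * mask
    dX <- dX + shift_rows(dpre %*% t(Wlist[[i]]), -o, T_, B)
  }
  list(dX = dX, dW = dW, db = colSums(dpre))
}

# ---- depthwise kernel-3 convolution over the first array axis --------------

# X is an array whose first dimension is the convolved axis; `ch_rep`
# expands a per-channel weight to the full array (see sea_forward_core).
dw3_fwd <- function(X, w, bias, ch_rep, ch_bias_rep) {
  d <- dim(X)
  Y <- array(ch_bias_rep(bias), d)
  for (j in 1:3) {
    Y <- Y + shift_axis1(X, j - 2L) * ch_rep(w[j, ])
  }
  Y
}

dw3_bwd <- function(dY, X, w, ch_rep, ch_sum) {
  d <- dim(dY)
  dX <- array(0, d)
  dw <- matrix(0, 3L, length(w[1L, ]))
  for (j in 1:3) {
    dX <- dX + shift_axis1(dY, -(j - 2L)) * ch_rep(w[j, ])
    dw[j, ] <- ch_sum(dY * shift_axis1(X, j - 2L))
  }
  list(dX = dX, dw = dw, db = ch_sum(dY))
}

# Shift an array along its first axis with zero padding.
shift_axis1 <- function(X, o) {
  if (o == 0L) {
    return(X)
  }
  d <- dim(X)
  n <- d[1L]
  Y <- array(0, d)
  if (abs(o) >= n) {
    return(Y)
  }
  idx <- seq_len(n)
  src <- idx + o
  keep <- src >= 1L & src <= n
  # flatten trick: operate on the matrix view (axis1 x rest)
  Xm <- X
  dim(Xm) <- c(n, prod(d[-1L]))
  Ym <- matrix(0, n, prod(d[-1L]))
  Ym[idx[keep], ] <- Xm[src[keep], , drop = FALSE]
  dim(Ym) <- d
  Ym
}

# ---- batched attention (C++ kernel wrappers) -------------------------------

attention_fwd <- function(Qc, Kc, Vc, h, scale) {
  .attn_forward(Qc, Kc, Vc, as.integer(h), scale)
}

attention_bwd <- function(dOc, Qc, Kc, Vc, A, h, scale) {
  .attn_backward(dOc, Qc, Kc, Vc, A, as.integer(h), scale)
}

# flat (B*T) x C sample-major layout
attention_fwd_flat <- function(Qm, Km, Vm, T_, h, scale) {
  .attn_forward_flat(Qm, Km, Vm, as.integer(T_), as.integer(h), scale)
}

attention_bwd_flat <- function(dOm, Qm, Km, Vm, A, T_, h, scale) {
  .attn_backward_flat(dOm, Qm, Km, Vm, A, as.integer(T_), as.integer(h), scale)
}
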