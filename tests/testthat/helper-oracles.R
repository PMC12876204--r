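# Independent straight-line reference implementations of the model
# stages, written with explicit loops directly from the layer equations.
# They share weights with a model but none of its code paths, and serve
# as oracles for the vectorized implementations.

oracle_softmax_vec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

oracle_layernorm_row <- function(v, gamma, beta, eps = 1e-5) {
  m <- mean(v)
  s <- mean((v - m)^2)
  (v - m) / sqrt(s + eps) * gamma + beta
}

# Post-norm transformer encoder on one T x d_model latent matrix.
oracle_encoder <- function(params, config, H) {
  dm <- config$d_model
  h <- config$h
  dk <- dm / h
  T_ <- nrow(H)
  for (l in seq_len(config$n_layers)) {
    p <- function(nm) params[[sprintf("enc%d_%s", l, nm)]]
    Q <- H %*% p("WQ")
    K <- H %*% p("WK")
    V <- H %*% p("WV")
    concat <- matrix(0, T_, dm)
    for (hd in seq_len(h)) {
      cols <- ((hd - 1) * dk + 1):(hd * dk)
      S <- matrix(0, T_, T_)
      for (i in seq_len(T_)) {
        for (j in seq_len(T_)) {
          S[i, j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dk)
        }
      }
      A <- t(apply(S, 1, oracle_softmax_vec))
      concat[, cols] <- A %*% V[, cols]
    }
    mhsa <- concat %*% p("WO")
    Hp <- H + mhsa
    for (i in seq_len(T_)) {
      Hp[i, ] <- oracle_layernorm_row(Hp[i, ], p("ln1_g"), p("ln1_b"))
    }
    ffn <- matrix(0, T_, dm)
    for (i in seq_len(T_)) {
      a <- pmax(Hp[i, ] %*% p("W1") + p("b1"), 0)
      ffn[i, ] <- a %*% p("W2") + p("b2")
    }
    H1 <- Hp + ffn
    for (i in seq_len(T_)) {
      H1[i, ] <- oracle_layernorm_row(H1[i, ], p("ln2_g"), p("ln2_b"))
    }
    H <- H1
  }
  H
}

# Selective-kernel branch on one T x d_model latent matrix, evaluation
# mode (batch-norm uses its running statistics: mean 0, variance 1 for a
# freshly initialized model).
oracle_sk <- function(params, config, H, run_mean = NULL, run_var = NULL) {
  dm <- config$d_model
  T_ <- nrow(H)
  ks <- config$kernel_set
  g <- config$conv_groups
  gsize <- dm / g
  Uk <- list()
  for (k in ks) {
    p <- (k - 1) / 2
    pre <- matrix(0, T_, dm)
    W <- lapply(seq_len(k), function(j) params[[sprintf("sk_k%d_W%d", k, j)]])
    for (t in seq_len(T_)) {
      for (cout in seq_len(dm)) {
        grp <- ceiling(cout / gsize)
        cins <- ((grp - 1) * gsize + 1):(grp * gsize)
        acc <- params[[sprintf("sk_k%d_b", k)]][cout]
        for (j in seq_len(k)) {
          ts <- t + (j - p - 1)
          if (ts >= 1 && ts <= T_) {
            acc <- acc + sum(H[ts, cins] * W[[j]][cins, cout])
          }
        }
        pre[t, cout] <- acc
      }
    }
    rm_ <- run_mean %||% rep(0, dm)
    rv_ <- run_var %||% rep(1, dm)
    bn <- sweep(sweep(pre, 2, rm_, "-"), 2, sqrt(rv_ + 1e-5), "/")
    bn <- sweep(sweep(bn, 2, params[[sprintf("sk_k%d_bn_g", k)]], "*"),
      2, params[[sprintf("sk_k%d_bn_b", k)]], "+"
    )
    Uk[[as.character(k)]] <- pmax(bn, 0)
  }
  U <- Reduce(`+`, Uk)
  z <- colMeans(U)
  s <- pmax(as.numeric(z %*% params$sk_W1), 0)
  logits <- as.numeric(s %*% params$sk_Wsel)
  alpha <- oracle_softmax_vec(logits)
  V <- matrix(0, T_, dm)
  for (i in seq_along(ks)) {
    V <- V + alpha[i] * Uk[[as.character(ks[i])]]
  }
  list(V = V, alpha = alpha)
}

# Squeeze-enhanced axial attention on one T x d_model latent matrix.
# Channel c maps to axial channel ca = floor((c-1)/W) + 1 and sub-band
# position w = (c-1) %% W + 1.
oracle_sea <- function(params, config, H) {
  dm <- config$d_model
  ca <- config$c_attn
  W_ <- dm / ca
  T_ <- nrow(H)
  X <- array(0, c(ca, T_, W_)) # (channel, row, col)
  for (c in seq_len(dm)) {
    cc <- (c - 1) %/% W_ + 1
    w <- (c - 1) %% W_ + 1
    X[cc, , w] <- H[, c]
  }
  dwconv_t <- function(A, wmat, bias) {
    # kernel-3 depthwise convolution along the row (time) axis
    Y <- array(0, dim(A))
    for (cc in seq_len(dim(A)[1])) {
      for (t in seq_len(dim(A)[2])) {
        acc <- bias[cc]
        for (j in 1:3) {
          ts <- t + (j - 2)
          if (ts >= 1 && ts <= dim(A)[2]) acc <- acc + wmat[j, cc] * A[cc, ts, ]
        }
        Y[cc, t, ] <- acc
      }
    }
    Y
  }
  Q <- dwconv_t(X, params$sea_wq, params$sea_bq)
  K <- dwconv_t(X, params$sea_wk, params$sea_bk)
  V <- dwconv_t(X, params$sea_wv, params$sea_bv)

  sq_w <- function(A) apply(A, c(1, 2), mean) # (ca, T)
  sq_t <- function(A) apply(A, c(1, 3), mean) # (ca, W)
  q_row <- sq_w(Q) + matrix(params$sea_pe_row, ca, T_, byrow = TRUE)
  k_row <- sq_w(K) + matrix(params$sea_pe_row, ca, T_, byrow = TRUE)
  v_row <- sq_w(V)
  q_col <- sq_t(Q) + matrix(params$sea_pe_col, ca, W_, byrow = TRUE)
  k_col <- sq_t(K) + matrix(params$sea_pe_col, ca, W_, byrow = TRUE)
  v_col <- sq_t(V)

  attn <- function(q, k, v) {
    n <- ncol(q)
    O <- matrix(0, nrow(q), n)
    for (i in seq_len(n)) {
      sc <- numeric(n)
      for (j in seq_len(n)) sc[j] <- sum(q[, i] * k[, j]) / sqrt(nrow(q))
      a <- oracle_softmax_vec(sc)
      O[, i] <- v %*% a
    }
    O
  }
  o_row <- attn(q_row, k_row, v_row) # (ca, T)
  o_col <- attn(q_col, k_col, v_col) # (ca, W)

  dw1d <- function(A, wmat, bias) {
    Y <- matrix(0, nrow(A), ncol(A))
    for (cc in seq_len(nrow(A))) {
      for (t in seq_len(ncol(A))) {
        acc <- bias[cc]
        for (j in 1:3) {
          ts <- t + (j - 2)
          if (ts >= 1 && ts <= ncol(A)) acc <- acc + wmat[j, cc] * A[cc, ts]
        }
        Y[cc, t] <- acc
      }
    }
    Y
  }
  O_row <- dw1d(o_row, params$sea_wrow, params$sea_brow)
  O_col <- dw1d(o_col, params$sea_wcol, params$sea_bcol)

  out <- matrix(0, T_, dm)
  for (t in seq_len(T_)) {
    for (w in seq_len(W_)) {
      y <- V[, t, w] + O_row[, t] + O_col[, w]
      pr <- as.numeric(t(params$sea_Wproj) %*% y) + params$sea_bproj
      if (config$sea_sigmoid) pr <- 1 / (1 + exp(-pr))
      for (cc in seq_len(ca)) {
        out[t, (cc - 1) * W_ + w] <- pr[cc]
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
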