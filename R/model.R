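# The window classifier: transformer encoder + selective-kernel branch +
# squeeze-enhanced axial attention + gated fusion + classification head.
#
# Data flow for one T x D window (batched internally):
#   H0 = X Wp + bp                         -- input projection
#   H1 = Encoder(H0)                       -- n_layers post-norm encoder layers
#   V_SK  = selective-kernel branch(H1)    -- multi-scale grouped convolutions
#   V_SEA = squeeze-axial attention(H1)    -- row (time) + column (sub-band)
#   G     = sigmoid(1x1 conv(H1))          -- per-timestep gate
#   V     = G * V_SK + (1 - G) * V_SEA     -- convex fusion
#   p     = softmax(W_o mean_t(V) + b_o)   -- pooled classification head
#
# Ablation variants reroute this flow (see build_variant()).

MODEL_VARIANTS <- c("FullModel", "No_SK", "No_SEA", "No_Gate", "No_Attn")

#' Model configuration
#'
#' All architecture hyperparameters in one validated object.
#'
#' @param n_classes Number of activity classes K (>= 2).
#' @param size Window length T in timesteps (default 200).
#' @param d_in Input channels D (default 3, tri-axial acceleration).
#' @param d_model Latent width (default 128).
#' @param n_layers Encoder layers (default 2).
#' @param h Attention heads (default 4); must divide `d_model`.
#' @param d_ff Feed-forward hidden width (default `2 * d_model`).
#' @param kernel_set Odd kernel sizes of the selective-kernel branch
#'   (default `c(1, 3, 5, 7)`).
#' @param d_s Width of the kernel-selection vector (default `d_model / 4`).
#' @param conv_groups Groups of the branch convolutions (default 4).
#' @param c_attn Channel count of the axial reshape (default 8); must
#'   divide `d_model`.
#' @param dropout Dropout rate during training (default 0.1).
#' @param use_positional_encoding Add a sinusoidal positional encoding to
#'   the projected input (default `FALSE`; the encoder is used without
#'   one by default).
#' @param sea_sigmoid Apply the sigmoid at the axial-attention output
#'   (default `TRUE`), constraining that branch to (0, 1).
#' @param variant One of `r paste(MODEL_VARIANTS, collapse = ", ")`.
#' @param seed Seed for weight initialization.
#' @return An object of class `ska_config`.
#' @export
model_config <- function(n_classes, size = 200, d_in = 3, d_model = 128,
                         n_layers = 2, h = 4, d_ff = 2 * d_model,
                         kernel_set = c(1, 3, 5, 7), d_s = d_model / 4,
                         conv_groups = 4, c_attn = 8, dropout = 0.1,
                         use_positional_encoding = FALSE,
                         sea_sigmoid = TRUE,
                         variant = "FullModel", seed = 1) {
  if (!is_whole(n_classes) || n_classes < 2) {
    stopf("model_config(): n_classes must be an integer >= 2")
  }
  if (d_model %% h != 0) {
    stopf("model_config(): d_model (%d) must be divisible by h (%d)", d_model, h)
  }
  if (d_model %% c_attn != 0) {
    stopf("model_config(): d_model (%d) must be divisible by c_attn (%d)", d_model, c_attn)
  }
  if (d_model %% conv_groups != 0) {
    stopf("model_config(): d_model (%d) must be divisible by conv_groups (%d)", d_model, conv_groups)
  }
  if (any(kernel_set %% 2 == 0)) {
    stopf("model_config(): kernel sizes must be odd (same-padded convolutions)")
  }
  if (!is_whole(d_s) || d_s < 1) {
    stopf("model_config(): d_s must be a positive integer")
  }
  variant <- match.arg(variant, MODEL_VARIANTS)
  structure(
    list(
      n_classes = as.integer(n_classes), size = as.integer(size),
      d_in = as.integer(d_in), d_model = as.integer(d_model),
      n_layers = as.integer(n_layers), h = as.integer(h),
      d_ff = as.integer(d_ff), kernel_set = as.integer(kernel_set),
      d_s = as.integer(d_s), conv_groups = as.integer(conv_groups),
      c_attn = as.integer(c_attn), dropout = dropout,
      use_positional_encoding = isTRUE(use_positional_encoding),
      sea_sigmoid = isTRUE(sea_sigmoid),
      variant = variant, seed = as.integer(seed)
    ),
    class = "ska_config"
  )
}

uniform_init <- function(fan_in, dims) {
  bound <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

has_sk <- function(config) config$variant %in% c("FullModel", "No_SEA", "No_Gate")
has_sea <- function(config) config$variant %in% c("FullModel", "No_SK", "No_Gate")
has_gate <- function(config) config$variant == "FullModel"

init_params <- function(config) {
  dm <- config$d_model
  with_local_seed(config$seed, {
    p <- list(
      Wp = uniform_init(config$d_in, c(config$d_in, dm)),
      bp = numeric(dm)
    )
    for (l in seq_len(config$n_layers)) {
      pre <- sprintf("enc%d_", l)
      p[[paste0(pre, "WQ")]] <- uniform_init(dm, c(dm, dm))
      p[[paste0(pre, "WK")]] <- uniform_init(dm, c(dm, dm))
      p[[paste0(pre, "WV")]] <- uniform_init(dm, c(dm, dm))
      p[[paste0(pre, "WO")]] <- uniform_init(dm, c(dm, dm))
      p[[paste0(pre, "ln1_g")]] <- rep(1, dm)
      p[[paste0(pre, "ln1_b")]] <- numeric(dm)
      p[[paste0(pre, "W1")]] <- uniform_init(dm, c(dm, config$d_ff))
      p[[paste0(pre, "b1")]] <- numeric(config$d_ff)
      p[[paste0(pre, "W2")]] <- uniform_init(config$d_ff, c(config$d_ff, dm))
      p[[paste0(pre, "b2")]] <- numeric(dm)
      p[[paste0(pre, "ln2_g")]] <- rep(1, dm)
      p[[paste0(pre, "ln2_b")]] <- numeric(dm)
    }
    if (has_sk(config)) {
      mask <- group_mask(dm, config$conv_groups)
      for (k in config$kernel_set) {
        fan <- (dm / config$conv_groups) * k
        for (o in seq_len(k)) {
          p[[sprintf("sk_k%d_W%d", k, o)]] <- uniform_init(fan, c(dm, dm)) * mask
        }
        p[[sprintf("sk_k%d_b", k)]] <- numeric(dm)
        p[[sprintf("sk_k%d_bn_g", k)]] <- rep(1, dm)
        p[[sprintf("sk_k%d_bn_b", k)]] <- numeric(dm)
      }
      p$sk_W1 <- uniform_init(dm, c(dm, config$d_s))
      p$sk_Wsel <- uniform_init(config$d_s, c(config$d_s, length(config$kernel_set)))
    }
    if (has_sea(config)) {
      ca <- config$c_attn
      for (nm in c("q", "k", "v")) {
        p[[paste0("sea_w", nm)]] <- uniform_init(3, c(3L, ca))
        p[[paste0("sea_b", nm)]] <- numeric(ca)
      }
      p$sea_pe_row <- numeric(config$size)
      p$sea_pe_col <- numeric(dm / ca)
      p$sea_wrow <- uniform_init(3, c(3L, ca))
      p$sea_brow <- numeric(ca)
      p$sea_wcol <- uniform_init(3, c(3L, ca))
      p$sea_bcol <- numeric(ca)
      p$sea_Wproj <- uniform_init(ca, c(ca, ca))
      p$sea_bproj <- numeric(ca)
    }
    if (has_gate(config)) {
      p$gate_w <- uniform_init(dm, c(dm, 1L))
      p$gate_b <- 0
    }
    p$Wo <- uniform_init(dm, c(dm, config$n_classes))
    p$bo <- numeric(config$n_classes)
    p
  })
}

init_state <- function(config) {
  st <- list()
  if (has_sk(config)) {
    for (k in config$kernel_set) {
      st[[sprintf("sk_k%d_mean", k)]] <- numeric(config$d_model)
      st[[sprintf("sk_k%d_var", k)]] <- rep(1, config$d_model)
    }
  }
  st
}

#' Construct a classifier with freshly initialized weights
#'
#' Linear and convolutional maps use fan-in uniform initialization;
#' normalization scales start at one, shifts and positional embeddings at
#' zero.  All draws are fixed by `config$seed`.
#'
#' @param config A [model_config()].
#' @return An object of class `ska_model`.
#' @export
ska_model <- function(config) {
  stopifnot(inherits(config, "ska_config"))
  params <- init_params(config)
  structure(
    list(config = config, params = params, state = init_state(config)),
    class = "ska_model"
  )
}

#' Number of trainable parameters of a model
#'
#' Grouped convolution weights count only their in-group (structurally
#' nonzero) entries.
#'
#' @param model A `ska_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "ska_model"))
  config <- model$config
  mask_n <- sum(group_mask(config$d_model, config$conv_groups))
  total <- 0
  for (nm in names(model$params)) {
    v <- model$params[[nm]]
    if (grepl("^sk_k\\d+_W\\d+$", nm)) {
      total <- total + mask_n
    } else {
      total <- total + length(v)
    }
  }
  as.integer(total)
}

#' @export
print.ska_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ska_model '%s'> T=%d D=%d d_model=%d layers=%d heads=%d kernels={%s} K=%d (%s parameters)\n",
    cfg$variant, cfg$size, cfg$d_in, cfg$d_model, cfg$n_layers, cfg$h,
    paste(cfg$kernel_set, collapse = ","), cfg$n_classes,
    format(n_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

sinusoidal_encoding <- function(T_, dm) {
  pos <- seq_len(T_) - 1L
  i <- seq_len(dm) - 1L
  angle <- outer(pos, 10000^(-(i %/% 2L) * 2 / dm))
  pe <- matrix(0, T_, dm)
  even <- (i %% 2L) == 0L
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

# ---- core forward ----------------------------------------------------------

# Xm: (B*T) x D sample-major matrix.  Returns logits and, on request, all
# caches required by the backward pass plus named intermediates.
core_forward <- function(params, config, state, Xm, B, training = FALSE,
                         keep_cache = FALSE, force_gate = NULL) {
  T_ <- config$size
  dm <- config$d_model
  cache <- list(Xm = Xm, B = B, training = training)

  H <- linear_fwd(Xm, params$Wp, params$bp)
  if (config$use_positional_encoding) {
    pe <- sinusoidal_encoding(T_, dm)
    H <- H + pe[rep(seq_len(T_), B), ]
  }
  cache$H0 <- H

  enc <- encoder_forward_core(params, config, H, B, training)
  H1 <- enc$H
  cache$enc <- enc$cache
  cache$H1 <- H1

  inter <- list()
  new_state <- state

  if (config$variant == "No_Attn") {
    head_in <- H1
  } else {
    vsk <- NULL
    vsea <- NULL
    if (has_sk(config)) {
      sk <- sk_forward_core(params, config, state, H1, B, training)
      vsk <- sk$V
      cache$sk <- sk$cache
      new_state <- utils::modifyList(new_state, sk$state)
      inter$alpha <- sk$alpha
    }
    if (has_sea(config)) {
      sea <- sea_forward_core(params, config, H1, B)
      vsea <- sea$V
      cache$sea <- sea$cache
      inter$A_row <- sea$A_row
      inter$A_col <- sea$A_col
    }
    if (config$variant == "No_SK") {
      head_in <- vsea
    } else if (config$variant == "No_SEA") {
      head_in <- vsk
    } else if (config$variant == "No_Gate") {
      head_in <- 0.5 * vsk + 0.5 * vsea
    } else {
      if (is.null(force_gate)) {
        gpre <- linear_fwd(H1, params$gate_w, params$gate_b)
        g <- sigmoid(as.numeric(gpre))
      } else {
        g <- rep(force_gate, nrow(H1))
      }
      head_in <- vsk * g + vsea * (1 - g)
      cache$gate <- list(g = g, forced = !is.null(force_gate))
      inter$gate <- matrix(g, T_, B)
    }
    inter$V_SK <- vsk
    inter$V_SEA <- vsea
    cache$vsk <- vsk
    cache$vsea <- vsea
  }

  grp <- rep(seq_len(B), each = T_)
  h_pool <- rowsum(head_in, grp) / T_
  logits <- linear_fwd(h_pool, params$Wo, params$bo)
  cache$head_in <- head_in
  cache$h_pool <- h_pool

  out <- list(
    logits = logits, prob = softmax_rows(logits),
    state = new_state, intermediates = inter, H1 = H1
  )
  if (keep_cache) out$cache <- cache
  out
}

encoder_forward_core <- function(params, config, H, B, training) {
  T_ <- config$size
  dm <- config$d_model
  h <- config$h
  scale <- 1 / sqrt(dm / h)
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("enc%d_", l)
    c_l <- list(H_in = H)
    Qm <- H %*% params[[paste0(pre, "WQ")]]
    Km <- H %*% params[[paste0(pre, "WK")]]
    Vm <- H %*% params[[paste0(pre, "WV")]]
    at <- attention_fwd_flat(Qm, Km, Vm, T_, h, scale)
    Om <- at$O
    MH <- Om %*% params[[paste0(pre, "WO")]]
    dr1 <- dropout_fwd(MH, config$dropout, training)
    ln1 <- layernorm_fwd(
      H + dr1$y, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]]
    )
    H2 <- ln1$y
    A1 <- linear_fwd(H2, params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
    rl <- relu_fwd(A1)
    FF <- linear_fwd(rl$y, params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
    dr2 <- dropout_fwd(FF, config$dropout, training)
    ln2 <- layernorm_fwd(
      H2 + dr2$y, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]]
    )
    c_l <- c(c_l, list(
      Qm = Qm, Km = Km, Vm = Vm, A = at$A, Om = Om,
      dr1 = dr1$mask, ln1 = ln1, H2 = H2, relu = rl, dr2 = dr2$mask, ln2 = ln2
    ))
    caches[[l]] <- c_l
    H <- ln2$y
  }
  list(H = H, cache = caches)
}

encoder_backward_core <- function(params, config, caches, dH, B) {
  T_ <- config$size
  h <- config$h
  scale <- 1 / sqrt(config$d_model / h)
  grads <- list()
  for (l in rev(seq_len(config$n_layers))) {
    pre <- sprintf("enc%d_", l)
    cl <- caches[[l]]
    lb2 <- layernorm_bwd(dH, cl$ln2, params[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- lb2$dgamma
    grads[[paste0(pre, "ln2_b")]] <- lb2$dbeta
    dres2 <- lb2$dX
    dFF <- dropout_bwd(dres2, cl$dr2)
    l2 <- linear_bwd(cl$relu$y, params[[paste0(pre, "W2")]], dFF)
    grads[[paste0(pre, "W2")]] <- l2$dW
    grads[[paste0(pre, "b2")]] <- l2$db
    dA1 <- l2$dX * cl$relu$mask
    l1 <- linear_bwd(cl$H2, params[[paste0(pre, "W1")]], dA1)
    grads[[paste0(pre, "W1")]] <- l1$dW
    grads[[paste0(pre, "b1")]] <- l1$db
    dH2 <- dres2 + l1$dX
    lb1 <- layernorm_bwd(dH2, cl$ln1, params[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- lb1$dgamma
    grads[[paste0(pre, "ln1_b")]] <- lb1$dbeta
    dres1 <- lb1$dX
    dMH <- dropout_bwd(dres1, cl$dr1)
    grads[[paste0(pre, "WO")]] <- crossprod(cl$Om, dMH)
    dOm <- dMH %*% t(params[[paste0(pre, "WO")]])
    ab <- attention_bwd_flat(dOm, cl$Qm, cl$Km, cl$Vm, cl$A, T_, h, scale)
    dQm <- ab$dQ
    dKm <- ab$dK
    dVm <- ab$dV
    H_in <- cl$H_in
    grads[[paste0(pre, "WQ")]] <- crossprod(H_in, dQm)
    grads[[paste0(pre, "WK")]] <- crossprod(H_in, dKm)
    grads[[paste0(pre, "WV")]] <- crossprod(H_in, dVm)
    dH <- dres1 +
      dQm %*% t(params[[paste0(pre, "WQ")]]) +
      dKm %*% t(params[[paste0(pre, "WK")]]) +
      dVm %*% t(params[[paste0(pre, "WV")]])
  }
  list(dH = dH, grads = grads)
}

sk_forward_core <- function(params, config, state, H1, B, training) {
  T_ <- config$size
  dm <- config$d_model
  ks <- config$kernel_set
  pmax_ <- (max(ks) - 1L) %/% 2L
  offsets_all <- seq.int(-pmax_, pmax_)
  Xsh <- lapply(offsets_all, function(o) shift_rows(H1, o, T_, B))
  names(Xsh) <- as.character(offsets_all)

  grp <- rep(seq_len(B), each = T_)
  U <- matrix(0, nrow(H1), dm)
  Uk <- vector("list", length(ks))
  kc <- vector("list", length(ks))
  st_new <- list()
  mask <- group_mask(dm, config$conv_groups)
  for (i in seq_along(ks)) {
    k <- ks[i]
    p <- (k - 1L) %/% 2L
    offs <- seq.int(-p, p)
    Wlist <- lapply(seq_len(k), function(o) params[[sprintf("sk_k%d_W%d", k, o)]] * mask)
    shifts <- list(offsets = offs, X = Xsh[as.character(offs)])
    pre_ <- gconv_fwd(H1, Wlist, params[[sprintf("sk_k%d_b", k)]], T_, B, shifts)
    bn <- batchnorm_fwd(
      pre_, params[[sprintf("sk_k%d_bn_g", k)]], params[[sprintf("sk_k%d_bn_b", k)]],
      state[[sprintf("sk_k%d_mean", k)]], state[[sprintf("sk_k%d_var", k)]],
      training
    )
    st_new[[sprintf("sk_k%d_mean", k)]] <- bn$run_mean
    st_new[[sprintf("sk_k%d_var", k)]] <- bn$run_var
    rl <- relu_fwd(bn$y)
    Uk[[i]] <- rl$y
    U <- U + rl$y
    kc[[i]] <- list(shifts = shifts, bn = bn, relu_mask = rl$mask)
  }
  z <- rowsum(U, grp) / T_
  s_pre <- z %*% params$sk_W1
  s <- s_pre * (s_pre > 0)
  sel_logits <- s %*% params$sk_Wsel
  alpha <- softmax_rows(sel_logits)
  alpha_e <- alpha[grp, , drop = FALSE]
  V <- matrix(0, nrow(H1), dm)
  for (i in seq_along(ks)) {
    V <- V + Uk[[i]] * alpha_e[, i]
  }
  list(
    V = V, alpha = alpha, state = st_new,
    cache = list(
      H1 = H1, Uk = Uk, kc = kc, z = z, s_pre = s_pre, s = s,
      alpha = alpha, grp = grp
    )
  )
}

sk_backward_core <- function(params, config, cache, dV, B) {
  T_ <- config$size
  ks <- config$kernel_set
  grp <- cache$grp
  alpha <- cache$alpha
  grads <- list()

  dalpha <- matrix(0, B, length(ks))
  for (i in seq_along(ks)) {
    dalpha[, i] <- rowsum(rowSums(dV * cache$Uk[[i]]), grp)
  }
  dsel <- alpha * (dalpha - rowSums(dalpha * alpha))
  grads$sk_Wsel <- crossprod(cache$s, dsel)
  ds <- (dsel %*% t(params$sk_Wsel)) * (cache$s_pre > 0)
  grads$sk_W1 <- crossprod(cache$z, ds)
  dz <- ds %*% t(params$sk_W1)
  dU <- dz[grp, , drop = FALSE] / T_

  mask <- group_mask(config$d_model, config$conv_groups)
  dH1 <- matrix(0, nrow(dV), config$d_model)
  alpha_e <- alpha[grp, , drop = FALSE]
  for (i in seq_along(ks)) {
    k <- ks[i]
    kc <- cache$kc[[i]]
    dUk <- dV * alpha_e[, i] + dU
    dbn_y <- dUk * kc$relu_mask
    bb <- batchnorm_bwd(dbn_y, kc$bn, params[[sprintf("sk_k%d_bn_g", k)]])
    grads[[sprintf("sk_k%d_bn_g", k)]] <- bb$dgamma
    grads[[sprintf("sk_k%d_bn_b", k)]] <- bb$dbeta
    Wlist <- lapply(seq_len(k), function(o) params[[sprintf("sk_k%d_W%d", k, o)]] * mask)
    cb <- gconv_bwd(bb$dX, Wlist, mask, T_, B, kc$shifts)
    for (o in seq_len(k)) {
      grads[[sprintf("sk_k%d_W%d", k, o)]] <- cb$dW[[o]]
    }
    grads[[sprintf("sk_k%d_b", k)]] <- cb$db
    dH1 <- dH1 + cb$dX
  }
  list(dH1 = dH1, grads = grads)
}

sea_forward_core <- function(params, config, H1, B) {
  T_ <- config$size
  dm <- config$d_model
  ca <- config$c_attn
  W_ <- dm %/% ca
  scale <- 1 / sqrt(ca)

  # channel-broadcast helpers for arrays of shape (T, W, Ca, B)
  rep4 <- function(v) rep(rep(v, each = T_ * W_), times = B)
  bias4 <- rep4
  sum4 <- function(X) {
    dim(X) <- c(T_ * W_, ca, B)
    rowSums(colSums(X)) # sum over axis 1 then over B -> per-channel
  }
  rep3t <- function(v) rep(rep(v, each = T_), times = B)
  sum3t <- function(X) {
    dim(X) <- c(T_, ca, B)
    rowSums(colSums(X))
  }
  rep3w <- function(v) rep(rep(v, each = W_), times = B)
  sum3w <- function(X) {
    dim(X) <- c(W_, ca, B)
    rowSums(colSums(X))
  }

  X4 <- array(mat2cube(H1, T_, B), c(T_, W_, ca, B))
  Q4 <- dw3_fwd(X4, params$sea_wq, params$sea_bq, rep4, bias4)
  K4 <- dw3_fwd(X4, params$sea_wk, params$sea_bk, rep4, bias4)
  V4 <- dw3_fwd(X4, params$sea_wv, params$sea_bv, rep4, bias4)

  squeeze_w <- function(A4) {
    p <- aperm(A4, c(2L, 1L, 3L, 4L))
    dim(p) <- c(W_, T_ * ca * B)
    array(colMeans(p), c(T_, ca, B))
  }
  squeeze_t <- function(A4) {
    Am <- A4
    dim(Am) <- c(T_, W_ * ca * B)
    array(colMeans(Am), c(W_, ca, B))
  }

  pe_r <- rep(params$sea_pe_row, times = ca * B)
  pe_c <- rep(params$sea_pe_col, times = ca * B)
  q_row <- squeeze_w(Q4) + pe_r
  k_row <- squeeze_w(K4) + pe_r
  v_row <- squeeze_w(V4)
  q_col <- squeeze_t(Q4) + pe_c
  k_col <- squeeze_t(K4) + pe_c
  v_col <- squeeze_t(V4)

  ar <- attention_fwd(q_row, k_row, v_row, 1L, scale)
  ac <- attention_fwd(q_col, k_col, v_col, 1L, scale)
  O_row <- dw3_fwd(ar$O, params$sea_wrow, params$sea_brow, rep3t, rep3t)
  O_col <- dw3_fwd(ac$O, params$sea_wcol, params$sea_bcol, rep3w, rep3w)

  broadcast_w <- function(Atcb) aperm(array(Atcb, c(T_, ca, B, W_)), c(1L, 4L, 2L, 3L))
  broadcast_t <- function(Awcb) aperm(array(Awcb, c(W_, ca, B, T_)), c(4L, 1L, 2L, 3L))

  Y4 <- V4 + broadcast_w(O_row) + broadcast_t(O_col)
  Ym <- aperm(Y4, c(1L, 2L, 4L, 3L))
  dim(Ym) <- c(T_ * W_ * B, ca)
  Pm <- linear_fwd(Ym, params$sea_Wproj, params$sea_bproj)
  Sm <- if (config$sea_sigmoid) sigmoid(Pm) else Pm

  S4 <- array(Sm, c(T_, W_, B, ca))
  S4 <- aperm(S4, c(1L, 2L, 4L, 3L))
  dim(S4) <- c(T_, dm, B)
  V_SEA <- cube2mat(S4)

  list(
    V = V_SEA, A_row = ar$A, A_col = ac$A,
    cache = list(
      X4 = X4, Q4 = Q4, K4 = K4, V4 = V4,
      q_row = q_row, k_row = k_row, v_row = v_row,
      q_col = q_col, k_col = k_col, v_col = v_col,
      ar = ar, ac = ac, O_row_pre = ar$O, O_col_pre = ac$O,
      Ym = Ym, Sm = Sm,
      helpers = list(
        rep4 = rep4, sum4 = sum4, rep3t = rep3t, sum3t = sum3t,
        rep3w = rep3w, sum3w = sum3w, squeeze_w = squeeze_w,
        squeeze_t = squeeze_t, broadcast_w = broadcast_w,
        broadcast_t = broadcast_t
      )
    )
  )
}

sea_backward_core <- function(params, config, cache, dVsea, B) {
  T_ <- config$size
  dm <- config$d_model
  ca <- config$c_attn
  W_ <- dm %/% ca
  scale <- 1 / sqrt(ca)
  hp <- cache$helpers
  grads <- list()

  dS3 <- mat2cube(dVsea, T_, B) # (T, dm, B)
  dS4 <- array(dS3, c(T_, W_, ca, B))
  dSm <- aperm(dS4, c(1L, 2L, 4L, 3L))
  dim(dSm) <- c(T_ * W_ * B, ca)
  if (config$sea_sigmoid) {
    dPm <- dSm * cache$Sm * (1 - cache$Sm)
  } else {
    dPm <- dSm
  }
  lb <- linear_bwd(cache$Ym, params$sea_Wproj, dPm)
  grads$sea_Wproj <- lb$dW
  grads$sea_bproj <- lb$db
  dY4 <- array(lb$dX, c(T_, W_, B, ca))
  dY4 <- aperm(dY4, c(1L, 2L, 4L, 3L))

  dV4 <- dY4
  # sum over the broadcast axes
  pR <- aperm(dY4, c(2L, 1L, 3L, 4L))
  dim(pR) <- c(W_, T_ * ca * B)
  dO_row <- array(colSums(pR), c(T_, ca, B))
  pC <- dY4
  dim(pC) <- c(T_, W_ * ca * B)
  dO_col <- array(colSums(pC), c(W_, ca, B))

  cr <- dw3_bwd(dO_row, cache$ar$O, params$sea_wrow, hp$rep3t, hp$sum3t)
  grads$sea_wrow <- cr$dw
  grads$sea_brow <- cr$db
  cc <- dw3_bwd(dO_col, cache$ac$O, params$sea_wcol, hp$rep3w, hp$sum3w)
  grads$sea_wcol <- cc$dw
  grads$sea_bcol <- cc$db

  abr <- attention_bwd(
    cr$dX, cache$q_row, cache$k_row, cache$v_row, cache$ar$A, 1L, scale
  )
  abc <- attention_bwd(
    cc$dX, cache$q_col, cache$k_col, cache$v_col, cache$ac$A, 1L, scale
  )

  sum_pe_t <- function(A) {
    dim(A) <- c(T_, ca * B)
    rowSums(A)
  }
  sum_pe_w <- function(A) {
    dim(A) <- c(W_, ca * B)
    rowSums(A)
  }
  grads$sea_pe_row <- sum_pe_t(abr$dQ + abr$dK)
  grads$sea_pe_col <- sum_pe_w(abc$dQ + abc$dK)

  dQ4 <- hp$broadcast_w(abr$dQ) / W_ + hp$broadcast_t(abc$dQ) / T_
  dK4 <- hp$broadcast_w(abr$dK) / W_ + hp$broadcast_t(abc$dK) / T_
  dV4 <- dV4 + hp$broadcast_w(abr$dV) / W_ + hp$broadcast_t(abc$dV) / T_

  dX4 <- array(0, dim(cache$X4))
  for (nm in c("q", "k", "v")) {
    dP <- switch(nm, q = dQ4, k = dK4, v = dV4)
    cb <- dw3_bwd(dP, cache$X4, params[[paste0("sea_w", nm)]], hp$rep4, hp$sum4)
    grads[[paste0("sea_w", nm)]] <- cb$dw
    grads[[paste0("sea_b", nm)]] <- cb$db
    dX4 <- dX4 + cb$dX
  }
  dim(dX4) <- c(T_, dm, B)
  list(dH1 = cube2mat(dX4), grads = grads)
}

# Backward through the whole model given d(logits); returns the parameter
# gradient list (same names as params).
core_backward <- function(params, config, cache, dlogits) {
  B <- cache$B
  T_ <- config$size
  grads <- list()
  lb <- linear_bwd(cache$h_pool, params$Wo, dlogits)
  grads$Wo <- lb$dW
  grads$bo <- lb$db
  grp <- rep(seq_len(B), each = T_)
  dhead <- lb$dX[grp, , drop = FALSE] / T_

  if (config$variant == "No_Attn") {
    dH1 <- dhead
  } else {
    dH1 <- matrix(0, nrow(dhead), config$d_model)
    dvsk <- NULL
    dvsea <- NULL
    if (config$variant == "No_SK") {
      dvsea <- dhead
    } else if (config$variant == "No_SEA") {
      dvsk <- dhead
    } else if (config$variant == "No_Gate") {
      dvsk <- 0.5 * dhead
      dvsea <- 0.5 * dhead
    } else {
      g <- cache$gate$g
      dvsk <- dhead * g
      dvsea <- dhead * (1 - g)
      if (!cache$gate$forced) {
        dg <- rowSums(dhead * (cache$vsk - cache$vsea))
        dgpre <- dg * g * (1 - g)
        grads$gate_w <- crossprod(cache$H1, matrix(dgpre))
        grads$gate_b <- sum(dgpre)
        dH1 <- dH1 + matrix(dgpre) %*% t(params$gate_w)
      }
    }
    if (!is.null(dvsk)) {
      skb <- sk_backward_core(params, config, cache$sk, dvsk, B)
      grads <- c(grads, skb$grads)
      dH1 <- dH1 + skb$dH1
    }
    if (!is.null(dvsea)) {
      seab <- sea_backward_core(params, config, cache$sea, dvsea, B)
      grads <- c(grads, seab$grads)
      dH1 <- dH1 + seab$dH1
    }
  }

  eb <- encoder_backward_core(params, config, cache$enc, dH1, B)
  grads <- c(grads, eb$grads)
  dH0 <- eb$dH
  pb <- linear_bwd(cache$Xm, params$Wp, dH0)
  grads$Wp <- pb$dW
  grads$bp <- pb$db
  grads
}

# ---- public forward-pass API -----------------------------------------------

as_batch_matrix <- function(x, config) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (length(d) != 3L || d[1L] != config$size || d[2L] != config$d_in) {
    stopf(
      "expected windows of shape (%d, %d), got (%s)",
      config$size, config$d_in, paste(d[1:2], collapse = ", ")
    )
  }
  list(Xm = cube2mat(x), B = d[3L])
}

#' Run the classifier forward
#'
#' @param model A `ska_model`.
#' @param x A `T x D` window matrix or a `(T, D, N)` array of windows
#'   (normalized; a drift warning is emitted otherwise).
#' @param intermediates Also return gate values, kernel-selection weights
#'   and axial attention maps.
#' @param force_gate Clamp the fusion gate to a constant in `[0, 1]`
#'   (diagnostic; e.g. 1 routes the selective-kernel branch alone
#'   through the head).
#' @param training Use training-time behavior (dropout, batch
#'   statistics).  Evaluation mode is deterministic.
#' @return A list with `prob` (N x K), `logits` (N x K) and, if
#'   requested, `intermediates`.
#' @export
model_forward <- function(model, x, intermediates = FALSE,
                          force_gate = NULL, training = FALSE) {
  stopifnot(inherits(model, "ska_model"))
  bt <- as_batch_matrix(x, model$config)
  mu <- mean(bt$Xm)
  sdv <- stats::sd(as.numeric(bt$Xm))
  if (abs(mu) > 0.5 || sdv < 0.3 || sdv > 3) {
    warnf(
      "model_forward(): input does not look z-scored (mean %.2f, sd %.2f)",
      mu, sdv
    )
  }
  out <- core_forward(
    model$params, model$config, model$state, bt$Xm, bt$B,
    training = training, force_gate = force_gate
  )
  res <- list(prob = out$prob, logits = out$logits)
  if (intermediates) res$intermediates <- out$intermediates
  res
}

#' Individual model stages
#'
#' Deterministic (evaluation-mode) access to each stage of the forward
#' computation, mainly for inspection and verification.  `project_input()`
#' maps windows to the latent sequence; `encoder_forward()` runs the
#' transformer encoder; `sk_forward()` the selective-kernel branch;
#' `sea_forward()` the squeeze-axial attention branch; `gate_fuse()` the
#' gated fusion; `classify()` the pooled classification head.
#'
#' @param model A `ska_model`.
#' @param x A `T x D` window or `(T, D, N)` array.
#' @param H A `T x d_model` latent matrix or `(T, d_model, N)` array.
#' @return Stage outputs with the temporal axis first; `sk_forward()`
#'   attaches the branch weights `alpha` as an attribute, `sea_forward()`
#'   the attention maps, `gate_fuse()` the gate.
#' @name model-stages
NULL

latent_batch <- function(H, config) {
  if (is.matrix(H)) H <- array(H, c(dim(H), 1L))
  d <- dim(H)
  if (d[1L] != config$size || d[2L] != config$d_model) {
    stopf("expected latents of shape (%d, %d)", config$size, config$d_model)
  }
  list(Hm = cube2mat(H), B = d[3L])
}

unbatch <- function(M, T_, B, drop1 = TRUE) {
  out <- mat2cube(M, T_, B)
  if (B == 1L && drop1) out <- out[, , 1L]
  out
}

#' @rdname model-stages
#' @export
project_input <- function(model, x) {
  bt <- as_batch_matrix(x, model$config)
  H <- linear_fwd(bt$Xm, model$params$Wp, model$params$bp)
  if (model$config$use_positional_encoding) {
    pe <- sinusoidal_encoding(model$config$size, model$config$d_model)
    H <- H + pe[rep(seq_len(model$config$size), bt$B), ]
  }
  unbatch(H, model$config$size, bt$B)
}

#' @rdname model-stages
#' @export
encoder_forward <- function(model, H) {
  lb <- latent_batch(H, model$config)
  enc <- encoder_forward_core(model$params, model$config, lb$Hm, lb$B, FALSE)
  unbatch(enc$H, model$config$size, lb$B)
}

#' @rdname model-stages
#' @export
sk_forward <- function(model, H) {
  if (!has_sk(model$config)) stopf("this variant has no selective-kernel branch")
  lb <- latent_batch(H, model$config)
  sk <- sk_forward_core(model$params, model$config, model$state, lb$Hm, lb$B, FALSE)
  out <- unbatch(sk$V, model$config$size, lb$B)
  attr(out, "alpha") <- sk$alpha
  out
}

#' @rdname model-stages
#' @export
sea_forward <- function(model, H) {
  if (!has_sea(model$config)) stopf("this variant has no axial-attention branch")
  lb <- latent_batch(H, model$config)
  sea <- sea_forward_core(model$params, model$config, lb$Hm, lb$B)
  out <- unbatch(sea$V, model$config$size, lb$B)
  attr(out, "A_row") <- sea$A_row
  attr(out, "A_col") <- sea$A_col
  out
}

#' @rdname model-stages
#' @param V_SK,V_SEA Branch outputs as returned by [sk_forward()] and
#'   [sea_forward()].
#' @param force_gate Optional constant gate override in `[0, 1]`.
#' @export
gate_fuse <- function(model, H, V_SK, V_SEA, force_gate = NULL) {
  if (!has_gate(model$config)) stopf("this variant has no fusion gate")
  lb <- latent_batch(H, model$config)
  vs <- latent_batch(V_SK, model$config)
  ve <- latent_batch(V_SEA, model$config)
  if (is.null(force_gate)) {
    g <- sigmoid(as.numeric(linear_fwd(lb$Hm, model$params$gate_w, model$params$gate_b)))
  } else {
    stopifnot(force_gate >= 0, force_gate <= 1)
    g <- rep(force_gate, nrow(lb$Hm))
  }
  fused <- vs$Hm * g + ve$Hm * (1 - g)
  out <- unbatch(fused, model$config$size, lb$B)
  attr(out, "gate") <- matrix(g, model$config$size, lb$B)
  out
}

#' @rdname model-stages
#' @param V Fused feature sequence (`T x d_model` or `(T, d_model, N)`).
#' @export
classify <- function(model, V) {
  lb <- latent_batch(V, model$config)
  grp <- rep(seq_len(lb$B), each = model$config$size)
  h_pool <- rowsum(lb$Hm, grp) / model$config$size
  logits <- linear_fwd(h_pool, model$params$Wo, model$params$bo)
  list(h_pool = h_pool, logits = logits, prob = softmax_rows(logits))
}
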