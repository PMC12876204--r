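# Training loop, stratified k-fold cross-validation and metrics.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 64).
#' @param epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience in epochs on the validation
#'   split (default 10); the best-validation weights are restored.
#' @param val_fraction Fraction of the training data held out for
#'   validation-based early stopping (default 0.1; 0 disables early
#'   stopping).
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment, shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64,
                         epochs = 100, patience = 10, val_fraction = 0.1,
                         folds = 5, seed = 1, verbose = FALSE) {
  if (learning_rate < 0) stopf("train_config(): learning_rate must be >= 0")
  if (folds < 2) stopf("train_config(): folds must be >= 2")
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), patience = as.integer(patience),
      val_fraction = val_fraction, folds = as.integer(folds),
      seed = as.integer(seed), verbose = isTRUE(verbose)
    ),
    class = "train_config"
  )
}

# Mean categorical cross-entropy and its logits gradient.
ce_loss <- function(logits, y) {
  B <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

stratified_split <- function(y, fraction, seed) {
  with_local_seed(seed, {
    val <- integer(0)
    for (k in unique(y)) {
      idx <- which(y == k)
      n_val <- floor(length(idx) * fraction)
      if (n_val > 0L) val <- c(val, sample(idx, n_val))
    }
    sort(val)
  })
}

# Predictions (class ids) in evaluation mode, in manageable chunks.
predict_ids <- function(model, x, chunk = 128L) {
  N <- dim(x)[3L]
  out <- integer(N)
  prob <- matrix(NA_real_, N, model$config$n_classes)
  for (s in seq.int(1L, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    bt <- as_batch_matrix(x[, , s:e, drop = FALSE], model$config)
    fw <- core_forward(model$params, model$config, model$state, bt$Xm, bt$B)
    prob[s:e, ] <- fw$prob
    out[s:e] <- max.col(fw$prob, ties.method = "first") - 1L
  }
  list(ids = out, prob = prob)
}

#' Train a classifier
#'
#' Minimizes categorical cross-entropy with Adam.  A stratified
#' validation split is carved from the training windows for early
#' stopping; the weights from the best validation epoch are restored.
#'
#' @param x Normalized windows, array `(T, D, N)`.
#' @param y Integer class ids (0-based), length N.
#' @param config A [model_config()].
#' @param train A [train_config()].
#' @param label_map Optional `imu_label_map` carried along for
#'   prediction in label space.
#' @return An object of class `ska_fit`: the trained `model`, the
#'   per-epoch `log` tibble and the realized epoch count.
#' @export
train_model <- function(x, y, config, train = train_config(),
                        label_map = NULL) {
  stopifnot(inherits(config, "ska_config"), inherits(train, "train_config"))
  N <- dim(x)[3L]
  if (N < 1L || length(y) != N) {
    stopf("train_model(): need one label per window")
  }
  model <- ska_model(config)

  val_idx <- if (train$val_fraction > 0) {
    stratified_split(y, train$val_fraction, train$seed + 7L)
  } else {
    integer(0)
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  x_tr <- x[, , tr_idx, drop = FALSE]
  y_tr <- y[tr_idx]
  has_val <- length(val_idx) > 0L
  if (has_val) {
    x_val <- x[, , val_idx, drop = FALSE]
    y_val <- y[val_idx]
  }

  opt <- adam_init(model$params)
  log_rows <- vector("list", train$epochs)
  best <- list(metric = Inf, params = model$params, state = model$state, epoch = 0L)
  wait <- 0L
  n_tr <- length(tr_idx)
  epochs_run <- 0L

  with_local_seed(train$seed, {
    for (epoch in seq_len(train$epochs)) {
      perm <- sample.int(n_tr)
      ep_loss <- 0
      n_batches <- 0L
      for (s in seq.int(1L, n_tr, by = train$batch_size)) {
        e <- min(s + train$batch_size - 1L, n_tr)
        bi <- perm[s:e]
        bt <- as_batch_matrix(x_tr[, , bi, drop = FALSE], config)
        fw <- core_forward(
          model$params, config, model$state, bt$Xm, bt$B,
          training = TRUE, keep_cache = TRUE
        )
        model$state <- fw$state
        ls <- ce_loss(fw$logits, y_tr[bi])
        if (!is.finite(ls$loss)) {
          stopf("train_model(): non-finite loss at epoch %d", epoch)
        }
        if (train$learning_rate > 0) {
          grads <- core_backward(model$params, config, fw$cache, ls$dlogits)
          upd <- adam_step(model$params, grads, opt, train$learning_rate)
          model$params <- upd$params
          opt <- upd$opt
        }
        ep_loss <- ep_loss + ls$loss
        n_batches <- n_batches + 1L
      }
      ep_loss <- ep_loss / n_batches
      row <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss,
        val_loss = NA_real_, val_accuracy = NA_real_
      )
      if (has_val) {
        pv <- predict_ids(model, x_val)
        vl <- ce_loss(log(pmax(pv$prob, 1e-12)), y_val)$loss
        va <- mean(pv$ids == y_val)
        row$val_loss <- vl
        row$val_accuracy <- va
        if (vl < best$metric - 1e-12) {
          best <- list(
            metric = vl, params = model$params, state = model$state,
            epoch = epoch
          )
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      log_rows[[epoch]] <- row
      epochs_run <- epoch
      if (train$verbose) {
        message(sprintf(
          "epoch %3d  loss %.4f  val_acc %s", epoch, ep_loss,
          if (has_val) sprintf("%.3f", row$val_accuracy) else "-"
        ))
      }
      if (has_val && wait >= train$patience) break
    }
  })
  if (has_val && best$epoch > 0L) {
    model$params <- best$params
    model$state <- best$state
  }
  structure(
    list(
      model = model, log = dplyr::bind_rows(log_rows[seq_len(epochs_run)]),
      epochs_run = epochs_run, best_epoch = if (has_val) best$epoch else epochs_run,
      train = train, label_map = label_map
    ),
    class = "ska_fit"
  )
}

#' @export
print.ska_fit <- function(x, ...) {
  cat(sprintf(
    "<ska_fit '%s'> %d epochs (best %d)%s\n",
    x$model$config$variant, x$epochs_run, x$best_epoch,
    if (!all(is.na(x$log$val_accuracy))) {
      sprintf(", best val accuracy %.3f", max(x$log$val_accuracy, na.rm = TRUE))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Predict activity classes for new windows
#'
#' @param object A `ska_fit`.
#' @param newdata Normalized windows `(T, D, N)`.
#' @param type `"class"` (labels if a label map is attached, else ids)
#'   or `"prob"`.
#' @param ... Unused.
#' @export
predict.ska_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  pv <- predict_ids(object$model, windows_to_array(newdata))
  if (type == "prob") {
    colnames(pv$prob) <- if (!is.null(object$label_map)) {
      object$label_map$class
    } else {
      as.character(seq_len(ncol(pv$prob)) - 1L)
    }
    return(pv$prob)
  }
  if (!is.null(object$label_map)) decode_labels(pv$ids, object$label_map) else pv$ids
}

#' Save or load a model checkpoint
#'
#' A checkpoint holds the trained weights, the full model configuration,
#' the batch-normalization running statistics and the label map, so a
#' saved model predicts identically after reloading.
#'
#' @param fit A `ska_fit` (or bare `ska_model`).
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "ska_fit")) fit$model else fit
  stopifnot(inherits(model, "ska_model"))
  saveRDS(
    list(
      params = model$params, config = model$config, state = model$state,
      label_map = if (inherits(fit, "ska_fit")) fit$label_map else NULL
    ),
    path
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- structure(
    list(config = ck$config, params = ck$params, state = ck$state),
    class = "ska_model"
  )
  structure(
    list(
      model = model, log = tibble::tibble(), epochs_run = NA_integer_,
      best_epoch = NA_integer_, train = NULL, label_map = ck$label_map
    ),
    class = "ska_fit"
  )
}

#' Classification metrics from true and predicted class ids
#'
#' Accuracy is the exact-match fraction; precision, recall and F1 are
#' macro-averaged over the K classes.  A class absent from both truth
#' and prediction contributes 0 to the macro averages, with a warning.
#'
#' @param truth,pred Integer vectors of 0-based class ids.
#' @param n_classes K.
#' @return An object of class `fold_metrics`: a list with `accuracy`,
#'   `precision`, `recall`, `f1` and the K x K `confusion` matrix
#'   (rows = truth).
#' @export
compute_metrics <- function(truth, pred, n_classes) {
  if (length(truth) != length(pred)) {
    stopf("compute_metrics(): truth and pred lengths differ")
  }
  if (any(c(truth, pred) < 0L) || any(c(truth, pred) >= n_classes)) {
    stopf("compute_metrics(): class id outside 0..%d", n_classes - 1L)
  }
  lv <- seq_len(n_classes) - 1L
  cm <- table(
    factor(truth, levels = lv),
    factor(pred, levels = lv)
  )
  cm <- matrix(as.integer(cm), n_classes, n_classes,
    dimnames = list(truth = lv, pred = lv)
  )
  tp <- diag(cm)
  row_tot <- rowSums(cm)
  col_tot <- colSums(cm)
  absent <- row_tot == 0L & col_tot == 0L
  if (any(absent)) {
    warnf(
      "compute_metrics(): %d class(es) absent from both truth and prediction",
      sum(absent)
    )
  }
  prec <- ifelse(col_tot > 0L, tp / col_tot, 0)
  rec <- ifelse(row_tot > 0L, tp / row_tot, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(
    list(
      accuracy = sum(tp) / sum(cm),
      precision = mean(prec), recall = mean(rec), f1 = mean(f1),
      confusion = cm
    ),
    class = "fold_metrics"
  )
}

#' @export
print.fold_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macro precision %.4f | recall %.4f | F1 %.4f (n = %d)\n",
    x$accuracy, x$precision, x$recall, x$f1, sum(x$confusion)
  ))
  invisible(x)
}

stratified_folds <- function(y, folds, seed) {
  assign_fold <- integer(length(y))
  with_local_seed(seed, {
    for (k in unique(y)) {
      idx <- which(y == k)
      if (length(idx) < folds) {
        stopf(
          "stratified_folds(): class %s has %d sample(s), fewer than %d folds",
          k, length(idx), folds
        )
      }
      assign_fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign_fold
}

#' Stratified k-fold cross-validation
#'
#' Splits windows into stratified folds (deterministic given the seed),
#' fits per-axis normalization statistics and trains a fresh model on
#' each fold's training portion only, and evaluates on the held-out
#' fold.  Fold averages are unweighted means.
#'
#' @param windows A `har_windows` object (unnormalized), or a list with
#'   `x` (array `(T, D, N)`) and `label_id`.
#' @param config A [model_config()]; its `n_classes` must cover every
#'   class id in the data.
#' @param train A [train_config()].
#' @param normalizer_scope `"fold"` (default) fits z-scoring statistics
#'   on each fold's training windows only; `"global"` restores the
#'   protocol-faithful but leaky variant that standardizes over the full
#'   dataset before splitting.
#' @return An object of class `har_cv`: per-fold metrics tibble,
#'   confusion matrices, fold assignment and the configurations used.
#' @export
run_cross_validation <- function(windows, config, train = train_config(),
                                 normalizer_scope = c("fold", "global")) {
  normalizer_scope <- match.arg(normalizer_scope)
  x <- windows$x
  y <- windows$label_id
  N <- dim(x)[3L]
  stopifnot(length(y) == N)
  if (max(y) + 1L > config$n_classes) {
    stopf(
      "run_cross_validation(): data has class id %d but the model has %d classes",
      max(y), config$n_classes
    )
  }
  folds <- train$folds
  fold_id <- stratified_folds(y, folds, train$seed)
  rows <- vector("list", folds)
  cms <- vector("list", folds)
  fits <- vector("list", folds)
  global_stats <- if (normalizer_scope == "global") fit_normalizer(x) else NULL
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    stats <- global_stats %||% fit_normalizer(x[, , tr, drop = FALSE])
    x_tr <- apply_normalizer(stats, x[, , tr, drop = FALSE])
    x_te <- apply_normalizer(stats, x[, , te, drop = FALSE])
    cfg <- config
    cfg$seed <- config$seed + f
    tc <- train
    tc$seed <- train$seed + 100L * f
    fit <- train_model(x_tr, y[tr], cfg, tc, label_map = windows$label_map)
    pv <- predict_ids(fit$model, x_te)
    m <- compute_metrics(y[te], pv$ids, config$n_classes)
    rows[[f]] <- tibble::tibble(
      fold = f, n_test = length(te), accuracy = m$accuracy,
      precision = m$precision, recall = m$recall, f1 = m$f1,
      epochs = fit$epochs_run
    )
    cms[[f]] <- m$confusion
    fits[[f]] <- fit$log
  }
  metrics <- dplyr::bind_rows(rows)
  structure(
    list(
      metrics = metrics,
      summary = dplyr::summarise(
        metrics,
        dplyr::across(c("accuracy", "precision", "recall", "f1"), mean)
      ),
      confusion = Reduce(`+`, cms),
      confusion_by_fold = cms,
      fold_id = fold_id,
      logs = fits,
      config = config, train = train,
      label_map = windows$label_map
    ),
    class = "har_cv"
  )
}

#' @export
print.har_cv <- function(x, ...) {
  cat(sprintf("<har_cv> %d-fold cross-validation\n", x$train$folds))
  print(x$metrics)
  cat(sprintf(
    "mean accuracy %.4f | macro F1 %.4f\n",
    x$summary$accuracy, x$summary$f1
  ))
  invisible(x)
}
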