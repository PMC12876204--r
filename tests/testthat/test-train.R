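# Training loop, metrics, and cross-validation mechanics.

test_that("metrics match hand-computed confusion arithmetic", {
  perfect <- compute_metrics(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), 3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # binary case: truth (1,1,0,0), prediction (1,0,0,0)
  m <- compute_metrics(c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L), 2)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, (2 / 3 + 1 / 1) / 2) # per-class 2/3 and 1/1
  expect_equal(m$recall, 0.75) # (2/2 + 1/2) / 2
  expect_equal(m$f1, (0.8 + 2 / 3) / 2, tolerance = 1e-10)
  expect_identical(as.integer(m$confusion), c(2L, 1L, 0L, 1L))

  # constant predictor on balanced 4-class data
  y4 <- rep(0:3, each = 5)
  expect_equal(compute_metrics(y4, rep(0L, 20), 4)$accuracy, 0.25)

  expect_warning(compute_metrics(c(0L, 0L), c(0L, 0L), 3), "absent")
  expect_error(compute_metrics(c(0L, 5L), c(0L, 1L), 3), "outside")
})

test_that("micro-averaged identities hold against a brute-force confusion oracle", {
  set.seed(21)
  for (rep in 1:5) {
    K <- sample(2:5, 1)
    n <- 60L
    truth <- sample(0:(K - 1), n, replace = TRUE)
    pred <- sample(0:(K - 1), n, replace = TRUE)
    m <- suppressWarnings(compute_metrics(truth, pred, K))
    brute <- matrix(0L, K, K)
    for (i in seq_len(n)) {
      brute[truth[i] + 1, pred[i] + 1] <- brute[truth[i] + 1, pred[i] + 1] + 1L
    }
    expect_identical(as.integer(m$confusion), as.integer(brute))
    expect_identical(sum(m$confusion), n)
    expect_equal(m$accuracy, sum(diag(brute)) / n)
    # micro precision = micro recall = accuracy in exact-match multi-class
    micro_p <- sum(diag(brute)) / sum(colSums(brute))
    micro_r <- sum(diag(brute)) / sum(rowSums(brute))
    expect_equal(micro_p, m$accuracy)
    expect_equal(micro_r, m$accuracy)
  }
})

test_that("a zero learning rate leaves the weights unchanged", {
  cfg <- tiny_config()
  set.seed(1)
  x <- array(rnorm(8 * 3 * 12), c(8, 3, 12))
  y <- rep(0:2, 4)
  fit <- train_model(x, y, cfg, train_config(
    learning_rate = 0, epochs = 1,
    val_fraction = 0, batch_size = 4, seed = 1
  ))
  m0 <- ska_model(cfg)
  for (nm in names(m0$params)) {
    expect_identical(fit$model$params[[nm]], m0$params[[nm]])
  }
})

test_that("initial loss on random labels is close to log K", {
  for (K in c(3, 6)) {
    cfg <- tiny_config(n_classes = K)
    m <- ska_model(cfg)
    set.seed(K)
    B <- 16
    x <- array(rnorm(8 * 3 * B), c(8, 3, B))
    y <- sample(0:(K - 1), B, replace = TRUE)
    bt <- imunet:::as_batch_matrix(x, cfg)
    fw <- imunet:::core_forward(m$params, cfg, m$state, bt$Xm, bt$B, training = TRUE)
    ls <- imunet:::ce_loss(fw$logits, y)
    expect_lt(abs(ls$loss - log(K)), 0.25 * log(K))
  }
})

test_that("a small separable problem is overfit to near-perfect training accuracy", {
  set.seed(3)
  n <- 32
  Tn <- 64
  t <- seq_len(Tn) / 20
  x <- array(0, c(Tn, 3, n))
  y <- integer(n)
  for (i in seq_len(n)) {
    f <- if (i %% 2 == 0) 0.8 else 2.2
    y[i] <- as.integer(i %% 2 == 0)
    x[, , i] <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), sin(2 * pi * f * t + 1)) +
      rnorm(3 * Tn, sd = 0.05)
  }
  cfg <- reduced_config(n_classes = 2, size = Tn, seed = 5)
  fit <- train_model(x, y, cfg, train_config(
    epochs = 60, batch_size = 16,
    val_fraction = 0, seed = 9
  ))
  # the training loss trend is downward overall
  expect_lt(mean(tail(fit$log$train_loss, 5)), mean(head(fit$log$train_loss, 5)))
  pv <- imunet:::predict_ids(fit$model, x)
  expect_gte(mean(pv$ids == y), 0.99)
})

test_that("stratified folds partition the data and are reproducible", {
  set.seed(31)
  y <- sample(0:3, 100, replace = TRUE)
  f1 <- imunet:::stratified_folds(y, 5, seed = 4)
  f2 <- imunet:::stratified_folds(y, 5, seed = 4)
  expect_identical(f1, f2)
  expect_identical(sort(unique(f1)), 1:5)
  # every sample appears in exactly one test fold
  expect_identical(length(f1), 100L)
  for (k in 0:3) {
    per_fold <- table(f1[y == k])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(imunet:::stratified_folds(c(0, 0, 1), 5, 1), "fewer than")
})

test_that("training and prediction are deterministic given seeds", {
  gen <- small_generator()
  ds <- generate_dataset(gen)
  w <- preprocess_sessions(ds$sessions, size = 64, stride = 32)
  st <- fit_normalizer(w$x)
  xn <- apply_normalizer(st, w$x)
  cfg <- tiny_config(n_classes = 3, size = 64, kernel_set = c(1, 3), dropout = 0.1)
  tc <- train_config(epochs = 2, batch_size = 32, seed = 12)
  f1 <- train_model(xn, w$label_id, cfg, tc)
  f2 <- train_model(xn, w$label_id, cfg, tc)
  expect_identical(f1$log, f2$log)
  p1 <- imunet:::predict_ids(f1$model, xn)
  p2 <- imunet:::predict_ids(f2$model, xn)
  expect_identical(p1$prob, p2$prob)
})

test_that("cross-validation runs per-fold or global normalization as requested", {
  set.seed(51)
  w <- list(
    x = array(rnorm(8 * 3 * 30, mean = 2, sd = 3), c(8, 3, 30)),
    label_id = rep(0:2, each = 10),
    label_map = encode_labels(c("a", "b", "c"))$map
  )
  cfg <- tiny_config()
  tc <- train_config(
    learning_rate = 0, epochs = 1, batch_size = 8,
    val_fraction = 0, folds = 2, seed = 3
  )
  cv_fold <- run_cross_validation(w, cfg, tc)
  cv_glob <- run_cross_validation(w, cfg, tc, normalizer_scope = "global")
  # same partition, same (untrained) model family; both produce metrics
  expect_identical(cv_fold$fold_id, cv_glob$fold_id)
  expect_identical(nrow(cv_fold$metrics), 2L)
  expect_identical(sum(cv_fold$confusion), 30L)
})

test_that("a reloaded checkpoint predicts identically", {
  set.seed(61)
  x <- array(rnorm(8 * 3 * 16), c(8, 3, 16))
  y <- rep(0:1, 8)
  lm <- encode_labels(c("jump", "walk"))$map
  fit <- train_model(x, y, tiny_config(n_classes = 2),
    train_config(epochs = 2, batch_size = 8, val_fraction = 0, seed = 4),
    label_map = lm
  )
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_identical(predict(back, x, type = "prob"), predict(fit, x, type = "prob"))
  expect_identical(predict(back, x), predict(fit, x))
})

test_that("tidiers and plots expose the fitted objects", {
  set.seed(41)
  x <- array(rnorm(8 * 3 * 20), c(8, 3, 20))
  y <- rep(0:1, 10)
  fit <- train_model(
    x, y, tiny_config(n_classes = 2),
    train_config(epochs = 2, batch_size = 8, val_fraction = 0.2, seed = 2)
  )
  td <- tidy(fit)
  expect_identical(names(td), c("epoch", "train_loss", "val_loss", "val_accuracy"))
  gl <- glance(fit)
  expect_identical(gl$epochs, fit$epochs_run)
  expect_s3_class(autoplot(fit), "ggplot")
})
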