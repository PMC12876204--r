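# Ablation variants: remove one architectural component at a time.
#
# FullModel  complete architecture.
# No_SK      selective-kernel branch removed; fusion bypassed, the head
#            consumes the axial-attention branch alone.
# No_SEA     axial attention removed; the head consumes the
#            selective-kernel branch alone.
# No_Gate    both branches kept but fused with a fixed 0.5/0.5 average
#            (gate parameters absent).
# No_Filter  architecture unchanged; the Butterworth + Savitzky-Golay
#            denoising stage is skipped (segmentation and normalization
#            retained).
# No_Attn    both branches and the gate absent; the encoder output is
#            pooled directly into the head.

ABLATION_VARIANTS <- c(
  "FullModel", "No_SK", "No_SEA", "No_Gate", "No_Filter", "No_Attn"
)

#' Build an ablation variant
#'
#' Returns the model configuration and preprocessing flags that realize
#' one named variant.  `No_Filter` touches only preprocessing; all other
#' variants touch only the architecture.
#'
#' @param name One of `r paste(ABLATION_VARIANTS, collapse = ", ")`.
#' @param config The base [model_config()].
#' @return A list with `name`, `config` (variant-adjusted) and
#'   `filter` (logical preprocessing flag).
#' @export
build_variant <- function(name, config) {
  stopifnot(inherits(config, "ska_config"))
  if (!name %in% ABLATION_VARIANTS) {
    stopf(
      "build_variant(): unknown variant '%s' (expected one of %s)",
      name, paste(ABLATION_VARIANTS, collapse = ", ")
    )
  }
  cfg <- config
  cfg$variant <- if (name == "No_Filter") "FullModel" else name
  list(name = name, config = cfg, filter = name != "No_Filter")
}

#' Run an ablation comparison on one dataset
#'
#' Trains every requested variant on the same sessions over the same
#' seeds, with a stratified train/test split per seed, and reports
#' per-run metrics.  The `No_Filter` variant re-runs preprocessing with
#' denoising disabled; all other variants share the filtered windows.
#'
#' @param sessions List of [imu_series()] (raw, unfiltered).
#' @param config Base [model_config()].
#' @param train A [train_config()]; its seed is combined with each
#'   element of `seeds`.
#' @param variants Character vector of variant names.
#' @param seeds Integer vector of replicate seeds (default 1:3).
#' @param test_fraction Held-out fraction per replicate (default 0.3).
#' @param size,stride,cutoff,order,window,polyorder Preprocessing
#'   parameters (see [preprocess_sessions()]).
#' @return An object of class `har_ablation`: tibble of per-run metrics
#'   plus a per-variant summary.
#' @export
run_ablation <- function(sessions, config, train = train_config(),
                         variants = ABLATION_VARIANTS, seeds = 1:3,
                         test_fraction = 0.3,
                         size = 200, stride = 100, cutoff = 2.5, order = 4,
                         window = 11, polyorder = 3) {
  prep <- function(filter) {
    preprocess_sessions(sessions,
      size = size, stride = stride, filter = filter,
      cutoff = cutoff, order = order, window = window, polyorder = polyorder
    )
  }
  filtered <- prep(TRUE)
  unfiltered <- if ("No_Filter" %in% variants) prep(FALSE) else NULL

  rows <- list()
  for (v in variants) {
    spec <- build_variant(v, config)
    data <- if (spec$filter) filtered else unfiltered
    for (sd in seeds) {
      te <- stratified_split(data$label_id, test_fraction, train$seed + sd)
      tr <- setdiff(seq_along(data$label_id), te)
      stats <- fit_normalizer(data$x[, , tr, drop = FALSE])
      x_tr <- apply_normalizer(stats, data$x[, , tr, drop = FALSE])
      x_te <- apply_normalizer(stats, data$x[, , te, drop = FALSE])
      cfg <- spec$config
      cfg$seed <- config$seed + sd
      tc <- train
      tc$seed <- train$seed + 10L * sd
      fit <- train_model(x_tr, data$label_id[tr], cfg, tc)
      pv <- predict_ids(fit$model, x_te)
      m <- compute_metrics(data$label_id[te], pv$ids, cfg$n_classes)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant = v, seed = sd, n_test = length(te),
        accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, f1 = m$f1, epochs = fit$epochs_run,
        n_parameters = n_parameters(fit$model)
      )
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      dplyr::across(c("accuracy", "precision", "recall", "f1"), mean),
      n_parameters = .data$n_parameters[1L],
      .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$variant, levels = ABLATION_VARIANTS))
  structure(
    list(runs = runs, summary = summary, seeds = seeds, config = config),
    class = "har_ablation"
  )
}

#' @export
print.har_ablation <- function(x, ...) {
  cat(sprintf(
    "<har_ablation> %d variants x %d seeds\n",
    length(unique(x$runs$variant)), length(x$seeds)
  ))
  print(x$summary)
  invisible(x)
}
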