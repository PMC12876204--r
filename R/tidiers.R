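# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `har_cv` from [run_cross_validation()].
#' @param ... Unused.
#' @return One row per fold with accuracy, macro precision/recall/F1.
#' @export
tidy.har_cv <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.har_cv
#' @return `glance()`: a one-row tibble of unweighted fold means.
#' @export
glance.har_cv <- function(x, ...) {
  tibble::add_column(x$summary, folds = x$train$folds, n = sum(x$metrics$n_test))
}

#' Tidy a training run
#'
#' @param x A `ska_fit` from [train_model()].
#' @param ... Unused.
#' @return The per-epoch log (train loss, validation loss/accuracy).
#' @export
tidy.ska_fit <- function(x, ...) {
  x$log
}

#' @rdname tidy.ska_fit
#' @export
glance.ska_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$model$config$variant,
    epochs = x$epochs_run,
    best_epoch = x$best_epoch,
    final_train_loss = x$log$train_loss[x$epochs_run],
    best_val_accuracy = if (all(is.na(x$log$val_accuracy))) {
      NA_real_
    } else {
      max(x$log$val_accuracy, na.rm = TRUE)
    },
    n_parameters = n_parameters(x$model)
  )
}

#' Tidy an ablation run
#'
#' @param x A `har_ablation` from [run_ablation()].
#' @param ... Unused.
#' @return One row per variant x seed.
#' @export
tidy.har_ablation <- function(x, ...) {
  x$runs
}

#' @rdname tidy.har_ablation
#' @export
glance.har_ablation <- function(x, ...) {
  x$summary
}

#' Plot a training run
#'
#' Loss and validation-accuracy trajectories over epochs.
#'
#' @param object A `ska_fit`.
#' @param ... Unused.
#' @export
autoplot.ska_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$log, -"epoch",
    names_to = "metric", values_to = "value"
  )
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot cross-validation metrics per fold
#'
#' @param object A `har_cv`.
#' @param ... Unused.
#' @export
autoplot.har_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$metrics,
    c("accuracy", "precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(min(df$value) * 0.95, 1)) +
    ggplot2::labs(x = "fold", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mean ablation metrics per variant
#'
#' @param object A `har_ablation`.
#' @param ... Unused.
#' @export
autoplot.har_ablation <- function(object, ...) {
  df <- object$summary
  df$variant <- factor(df$variant, levels = ABLATION_VARIANTS)
  ggplot2::ggplot(df, ggplot2::aes(.data$variant, .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_point(
      data = object$runs,
      ggplot2::aes(factor(.data$variant, levels = ABLATION_VARIANTS), .data$accuracy)
    ) +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param cm A K x K confusion matrix (rows = truth), e.g.
#'   `har_cv$confusion`.
#' @param labels Optional class labels.
#' @export
plot_confusion <- function(cm, labels = NULL) {
  K <- nrow(cm)
  labels <- labels %||% rownames(cm) %||% as.character(seq_len(K) - 1L)
  df <- expand.grid(truth = labels, pred = labels, stringsAsFactors = FALSE)
  df$n <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(labels)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal()
}
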