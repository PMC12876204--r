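# Declarative run configuration: YAML in, validated and fully defaulted
# list out, with a content fingerprint that is stable under key
# reordering.

default_run_config_values <- function() {
  list(
    generator = list(
      classes = c("downstairs", "marching", "running", "standing", "upstairs", "walking"),
      fs = 20, noise_sd = 0.08, drift_amplitude = 0.05, drift_period = 30,
      envelope_depth = 0.2, envelope_period = 8,
      segment_min = 30, segment_max = 45, n_sessions = 6, seed = 2024
    ),
    preprocess = list(
      fs = 20, size = 200, stride = 100, filter = TRUE,
      cutoff = 2.5, order = 4, window = 11, polyorder = 3
    ),
    model = list(
      d_model = 128, n_layers = 2, h = 4, d_ff = 256,
      kernel_set = c(1, 3, 5, 7), d_s = 32, conv_groups = 4, c_attn = 8,
      dropout = 0.1, use_positional_encoding = FALSE, sea_sigmoid = TRUE,
      variant = "FullModel", seed = 1
    ),
    train = list(
      learning_rate = 0.001, batch_size = 64, epochs = 100, patience = 10,
      val_fraction = 0.1, folds = 5, seed = 1
    ),
    paths = list(input = "", output = "")
  )
}

# Recursively sort list keys so semantically equal configs hash equally.
canonicalize <- function(x) {
  if (is.list(x)) {
    x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else {
    x
  }
}

#' Fingerprint of a run configuration
#'
#' A content hash over the recursively key-sorted configuration, so two
#' configs that differ only in key order share a fingerprint and any
#' changed value changes it.
#'
#' @param config A run-config list.
#' @return Character scalar.
#' @export
config_fingerprint <- function(config) {
  cfg <- config
  cfg$fingerprint <- NULL
  rlang::hash(canonicalize(cfg))
}

merge_validate <- function(user, defaults, path = "") {
  if (length(user) == 0L) {
    return(defaults)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stopf(
      "load_run_config(): unknown key(s): %s",
      paste0(path, unknown, collapse = ", ")
    )
  }
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_validate(user[[nm]], defaults[[nm]], paste0(path, nm, "."))
    } else {
      v <- user[[nm]]
      d <- defaults[[nm]]
      if (is.numeric(d) && !is.numeric(v)) {
        stopf("load_run_config(): key %s%s must be numeric", path, nm)
      }
      if (is.logical(d) && !is.logical(v)) {
        stopf("load_run_config(): key %s%s must be logical", path, nm)
      }
      out[[nm]] <- v
    }
  }
  out
}

validate_run_config <- function(cfg) {
  m <- cfg$model
  if (m$d_model %% m$h != 0) {
    stopf(
      "run config: model.d_model (%d) must be divisible by model.h (%d)",
      m$d_model, m$h
    )
  }
  if (m$d_model %% m$c_attn != 0) {
    stopf(
      "run config: model.d_model (%d) must be divisible by model.c_attn (%d)",
      m$d_model, m$c_attn
    )
  }
  if (cfg$preprocess$cutoff >= cfg$preprocess$fs / 2) {
    stopf("run config: preprocess.cutoff must be below the Nyquist frequency")
  }
  if (cfg$train$learning_rate < 0) {
    stopf("run config: train.learning_rate must be >= 0")
  }
  if (cfg$generator$noise_sd < 0) {
    stopf("run config: generator.noise_sd must be >= 0")
  }
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with sections `generator`, `preprocess`, `model`,
#' `train` and `paths`, fills in documented defaults, rejects unknown
#' keys, validates cross-field invariants and attaches a content
#' fingerprint.  An empty (or absent section) file yields the full
#' default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list with class `run_config` and a `fingerprint`
#'   field.
#' @export
load_run_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else {
    yaml::read_yaml(path) %||% list()
  }
  cfg <- merge_validate(user, default_run_config_values())
  validate_run_config(cfg)
  cfg$fingerprint <- config_fingerprint(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Instantiate module configurations from a run configuration
#'
#' @param cfg A `run_config`.
#' @param n_classes Class count for the model section.
#' @return A list with `generator`, `model` and `train` objects.
#' @export
run_config_objects <- function(cfg, n_classes = length(cfg$generator$classes)) {
  g <- cfg$generator
  m <- cfg$model
  t <- cfg$train
  list(
    generator = generator_config(
      classes = g$classes, fs = g$fs, noise_sd = g$noise_sd,
      drift_amplitude = g$drift_amplitude, drift_period = g$drift_period,
      envelope_depth = g$envelope_depth, envelope_period = g$envelope_period,
      segment_range = c(g$segment_min, g$segment_max),
      n_sessions = g$n_sessions, seed = g$seed
    ),
    model = model_config(
      n_classes = n_classes, size = cfg$preprocess$size, d_in = 3,
      d_model = m$d_model, n_layers = m$n_layers, h = m$h, d_ff = m$d_ff,
      kernel_set = m$kernel_set, d_s = m$d_s, conv_groups = m$conv_groups,
      c_attn = m$c_attn, dropout = m$dropout,
      use_positional_encoding = m$use_positional_encoding,
      sea_sigmoid = m$sea_sigmoid, variant = m$variant, seed = m$seed
    ),
    train = train_config(
      learning_rate = t$learning_rate, batch_size = t$batch_size,
      epochs = t$epochs, patience = t$patience,
      val_fraction = t$val_fraction, folds = t$folds, seed = t$seed
    )
  )
}
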