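# Shared fixtures built in code.

# A tiny model configuration that exercises every component cheaply.
tiny_config <- function(...) {
  defaults <- list(
    n_classes = 3, size = 8, d_in = 3, d_model = 8, n_layers = 2, h = 2,
    d_ff = 12, kernel_set = c(1, 3), d_s = 4, conv_groups = 2, c_attn = 2,
    dropout = 0, seed = 42
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# The reduced CPU-scale configuration used for training experiments.
reduced_config <- function(n_classes = 6, ...) {
  defaults <- list(
    n_classes = n_classes, size = 200, d_in = 3, d_model = 32, n_layers = 2,
    h = 2, d_ff = 64, kernel_set = c(1, 3, 5, 7), d_s = 8, conv_groups = 4,
    c_attn = 8, dropout = 0, seed = 1
  )
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

random_windows <- function(config, n, seed = 1) {
  set.seed(seed)
  array(rnorm(config$size * config$d_in * n), c(config$size, config$d_in, n))
}

random_latent <- function(config, seed = 1) {
  set.seed(seed)
  matrix(rnorm(config$size * config$d_model), config$size, config$d_model)
}

random_triple <- function(seed = 1) {
  set.seed(seed)
  list(
    ax = runif(1, -15, 15), ay = runif(1, -15, 15), az = runif(1, -15, 15),
    gx = runif(1, -1900, 1900), gy = runif(1, -1900, 1900), gz = runif(1, -1900, 1900),
    roll = runif(1, -170, 170), pitch = runif(1, -170, 170), yaw = runif(1, -170, 170),
    temp = runif(1, 0, 40)
  )
}

# Drop non-dim attributes (attached diagnostics) from a stage output.
unclass_strip <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# Small fast synthetic dataset for training smoke tests.
small_generator <- function(K = 3, seed = 11) {
  generator_config(
    classes = c("run", "stand", "walk")[seq_len(K)],
    fundamentals = c(2.0, 0.6, 1.2)[seq_len(K)],
    segment_range = c(25, 30), n_sessions = 3, seed = seed
  )
}
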