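# Synthetic IMU session generator.
#
# Emulates waist-worn tri-axial accelerometer recordings of quasi-periodic
# activities: each class is a harmonic series at a class-specific
# fundamental frequency, mixed across axes by a class-specific rotation
# (so classes differ in direction, not just spectrum), modulated by a slow
# amplitude envelope, and corrupted by additive Gaussian noise and a slow
# sinusoidal baseline drift.  Sessions concatenate activity segments with
# per-timestep labels, so label transitions occur only at segment
# boundaries.

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Configuration of the synthetic IMU generator
#'
#' Defaults emulate a six-activity waist-mounted accelerometer protocol at
#' 20 Hz: distinct fundamentals between 0.5 and 2.3 Hz (inside the 2.5 Hz
#' low-pass band of the conditioning pipeline), three harmonics with
#' geometrically decaying amplitudes, one distinct axis-mixing rotation
#' per class, 8 percent-of-amplitude sensor noise and a slow baseline
#' drift.
#'
#' @param classes Character vector of class names (K classes).
#' @param fs Sampling rate in Hz.
#' @param fundamentals Per-class fundamental frequency in Hz (distinct).
#' @param amplitudes Per-class peak amplitude in g.
#' @param harmonics Relative amplitudes of the harmonic series (first
#'   entry is the fundamental).
#' @param rotations List of per-class 3x3 orthonormal axis-mixing
#'   matrices; defaults to rotations of increasing angle about the
#'   (1,1,1) diagonal.
#' @param envelope_depth,envelope_period Amplitude-modulation depth
#'   (fraction) and period (s).
#' @param noise_sd Additive Gaussian noise standard deviation (g).
#' @param drift_amplitude,drift_period Baseline drift amplitude (g) and
#'   period (s).
#' @param segment_range Min/max activity-segment duration (s).
#' @param n_sessions Number of sessions in a dataset.
#' @param seed Master seed; per-session seeds are derived by fixed
#'   integer offsets.
#' @return An object of class `imu_generator_config`.
#' @export
generator_config <- function(classes = c(
                               "downstairs", "marching", "running",
                               "standing", "upstairs", "walking"
                             ),
                             fs = 20,
                             fundamentals = NULL,
                             amplitudes = NULL,
                             harmonics = c(1, 0.5, 0.25),
                             rotations = NULL,
                             envelope_depth = 0.2,
                             envelope_period = 8,
                             noise_sd = 0.08,
                             drift_amplitude = 0.05,
                             drift_period = 30,
                             segment_range = c(30, 45),
                             n_sessions = 6,
                             seed = 2024) {
  K <- length(classes)
  if (K < 1L) stopf("generator_config(): need at least one class")
  if (is.null(fundamentals)) {
    fundamentals <- seq(0.5, 2.3, length.out = max(K, 2L))[seq_len(K)]
  }
  if (is.null(amplitudes)) {
    amplitudes <- rep(c(1, 0.8, 1.2, 0.6, 1, 0.9), length.out = K)
  }
  if (anyDuplicated(fundamentals)) {
    stopf("generator_config(): class fundamentals must be distinct")
  }
  if (noise_sd < 0) stopf("generator_config(): noise_sd must be >= 0")
  if (is.null(rotations)) {
    rotations <- lapply(seq_len(K), function(k) {
      rotation_about_axis(c(1, 1, 1), (k - 1) * pi / (K + 1))
    })
  }
  for (R in rotations) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8) {
      stopf("generator_config(): rotations must be orthonormal")
    }
  }
  structure(
    list(
      classes = as.character(classes), fs = fs,
      fundamentals = fundamentals, amplitudes = amplitudes,
      harmonics = harmonics, rotations = rotations,
      envelope_depth = envelope_depth, envelope_period = envelope_period,
      noise_sd = noise_sd, drift_amplitude = drift_amplitude,
      drift_period = drift_period, segment_range = segment_range,
      n_sessions = n_sessions, seed = seed
    ),
    class = "imu_generator_config"
  )
}

# Clean (noise-free, drift-free) class template at time points t (seconds).
class_template <- function(config, k, t, phases) {
  f0 <- config$fundamentals[k]
  h <- config$harmonics
  base <- sapply(seq_along(h), function(m) h[m] * sin(2 * pi * m * f0 * t + phases[m]))
  quad <- sapply(seq_along(h), function(m) h[m] * cos(2 * pi * m * f0 * t + phases[m]))
  u <- cbind(rowSums(base), rowSums(quad), 0.3 * sin(2 * pi * f0 * t + phases[1L]))
  env <- 1 + config$envelope_depth *
    sin(2 * pi * t / config$envelope_period + phases[1L] / 2)
  amp <- config$amplitudes[k]
  (u * env) %*% t(config$rotations[[k]]) * amp
}

#' Generate one labeled synthetic session
#'
#' Concatenates one segment per class (in seeded random order, with
#' seeded random durations inside `segment_range`) and adds noise and
#' drift.  Fully determined by `(config, seed)`.
#'
#' @param config An [generator_config()].
#' @param seed Session seed.
#' @param id Session identifier.
#' @param return_clean Also return the noise-free template (for
#'   diagnostics).
#' @return An [imu_series()]; if `return_clean = TRUE`, an attribute
#'   `clean` holds the template matrix.
#' @export
generate_session <- function(config, seed = config$seed, id = "session",
                             return_clean = FALSE) {
  stopifnot(inherits(config, "imu_generator_config"))
  K <- length(config$classes)
  with_local_seed(seed, {
    order_k <- sample.int(K)
    durations <- stats::runif(K, config$segment_range[1L], config$segment_range[2L])
    seg_mats <- vector("list", K)
    seg_labels <- vector("list", K)
    t_offset <- 0
    for (j in seq_len(K)) {
      k <- order_k[j]
      n <- max(1L, round(durations[j] * config$fs))
      t <- t_offset + seq_len(n) / config$fs
      phases <- stats::runif(length(config$harmonics), 0, 2 * pi)
      seg_mats[[j]] <- class_template(config, k, t, phases)
      seg_labels[[j]] <- rep(config$classes[k], n)
      t_offset <- t_offset + n / config$fs
    }
    clean <- do.call(rbind, seg_mats)
    L <- nrow(clean)
    tt <- seq_len(L) / config$fs
    drift_phase <- stats::runif(3, 0, 2 * pi)
    drift <- sapply(1:3, function(a) {
      config$drift_amplitude * sin(2 * pi * tt / config$drift_period + drift_phase[a])
    })
    noise <- matrix(stats::rnorm(L * 3, sd = config$noise_sd), L, 3)
    samples <- clean + drift + noise
    colnames(samples) <- c("ax", "ay", "az")
    out <- imu_series(samples, unlist(seg_labels), config$fs, id = id)
    if (return_clean) attr(out, "clean") <- clean + drift
    out
  })
}

#' Generate a full synthetic dataset
#'
#' Two modes: `"session"` (default) produces `n_sessions` continuous
#' sessions with per-timestep labels and activity transitions;
#' `"record"` emulates a short-recording protocol (e.g. one sport
#' movement per file) with `records_per_class` single-label recordings
#' per class.
#'
#' @param config An [generator_config()].
#' @param mode `"session"` or `"record"`.
#' @param records_per_class Recordings per class in record mode
#'   (default 30).
#' @param record_duration Duration in seconds of one recording in record
#'   mode (default 12).
#' @return A list with `sessions` (list of [imu_series()]) and
#'   `manifest` (tibble of per-class label counts).
#' @export
generate_dataset <- function(config, mode = c("session", "record"),
                             records_per_class = 30, record_duration = 12) {
  stopifnot(inherits(config, "imu_generator_config"))
  mode <- match.arg(mode)
  if (mode == "session") {
    sessions <- lapply(seq_len(config$n_sessions), function(i) {
      generate_session(config,
        seed = config$seed + 1000L * i,
        id = sprintf("session_%02d", i)
      )
    })
  } else {
    K <- length(config$classes)
    cfg1 <- config
    cfg1$segment_range <- c(record_duration, record_duration)
    sessions <- list()
    for (k in seq_len(K)) {
      cfgk <- cfg1
      cfgk$classes <- config$classes[k]
      cfgk$fundamentals <- config$fundamentals[k]
      cfgk$amplitudes <- config$amplitudes[k]
      cfgk$rotations <- config$rotations[k]
      for (r in seq_len(records_per_class)) {
        s <- generate_session(cfgk,
          seed = config$seed + 1000L * ((k - 1L) * records_per_class + r),
          id = sprintf("%s_rec%02d", config$classes[k], r)
        )
        s$labels <- config$classes[k] # one label per recording
        sessions[[length(sessions) + 1L]] <- s
      }
    }
  }
  counts <- table(unlist(lapply(sessions, function(s) {
    if (length(s$labels) == 1L) s$labels else s$labels
  })))
  manifest <- tibble::tibble(
    class = names(counts),
    n = as.integer(counts),
    unit = if (mode == "record") "records" else "timesteps"
  )
  if (mode == "record") {
    recs <- vapply(sessions, function(s) s$labels[[1L]], character(1))
    manifest <- dplyr::count(tibble::tibble(class = recs), .data$class, name = "n")
    manifest$unit <- "records"
  }
  list(sessions = sessions, manifest = manifest, mode = mode, config = config)
}

#' Center-crop or pad single-label recordings to a fixed window length
#'
#' Recording protocols that store one movement per file are windowed by
#' center-cropping recordings longer than `size` and edge-padding (repeat
#' of the boundary sample) shorter ones, yielding exactly one window per
#' recording.
#'
#' @param sessions List of single-label [imu_series()] recordings.
#' @param size Window length (default 200).
#' @return A tibble in the [segment_windows()] layout.
#' @export
records_to_windows <- function(sessions, size = 200) {
  rows <- lapply(sessions, function(s) {
    L <- nrow(s$samples)
    if (L >= size) {
      off <- (L - size) %/% 2L
      w <- s$samples[(off + 1L):(off + size), , drop = FALSE]
    } else {
      pre <- (size - L) %/% 2L
      post <- size - L - pre
      w <- rbind(
        s$samples[rep(1L, pre), , drop = FALSE],
        s$samples,
        s$samples[rep(L, post), , drop = FALSE]
      )
    }
    lab <- if (length(s$labels) == 1L) s$labels else s$labels[[1L]]
    tibble::tibble(
      session = s$id, start = 0L, window = list(w),
      labels = list(rep(lab, size))
    )
  })
  dplyr::bind_rows(rows)
}

#' Serialize a series through the binary sensor protocol
#'
#' Encodes the accelerometer channels of a series as JY61-style binary
#' frames (gyro/angle channels zero unless present), the end-to-end path
#' a hardware stream would take.  Values beyond the channel full scale
#' are clipped with a warning.
#'
#' @param series An [imu_series()] whose first three columns are
#'   acceleration in g.
#' @return A raw vector (33 bytes per sample).
#' @export
serialize_to_packets <- function(series) {
  stopifnot(inherits(series, "imu_series"))
  a <- series$samples[, 1:3, drop = FALSE]
  fs_g <- FULL_SCALE[["accel"]]
  lim <- fs_g * 32766.5 / 32768 # largest value that quantizes within range
  if (any(abs(a) > lim)) {
    warnf("serialize_to_packets(): %d acceleration values clipped to the +/-16 g range", sum(abs(a) > lim))
    a <- pmin(pmax(a, -lim), lim)
  }
  frames <- tibble::tibble(
    index = seq_len(nrow(a)) - 1L,
    ax = a[, 1L], ay = a[, 2L], az = a[, 3L],
    gx = 0, gy = 0, gz = 0, roll = 0, pitch = 0, yaw = 0, temp = 0
  )
  encode_frames(frames)
}

#' Classify windows by their dominant spectral peak
#'
#' A deliberately simple reference classifier: each window is assigned
#' the class whose fundamental frequency is closest to the periodogram
#' peak of the window's highest-variance axis.  Used to verify that a
#' synthetic dataset is learnable at all, independent of any neural
#' model.
#'
#' @param windows List of `T x D` matrices or a `(T, D, N)` array.
#' @param fs Sampling rate (Hz).
#' @param fundamentals Per-class fundamental frequencies (Hz), in class
#'   id order.
#' @return Integer vector of predicted 0-based class ids.
#' @export
spectral_peak_classify <- function(windows, fs, fundamentals) {
  x <- windows_to_array(windows)
  Tn <- dim(x)[1L]
  freqs <- (seq_len(Tn %/% 2L)) * fs / Tn
  apply(x, 3L, function(w) {
    v <- apply(w, 2L, stats::var)
    col <- w[, which.max(v)]
    sp <- Mod(stats::fft(col - mean(col)))[2:(Tn %/% 2L + 1L)]
    fpeak <- freqs[which.max(sp)]
    which.min(abs(fundamentals - fpeak)) - 1L
  })
}
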