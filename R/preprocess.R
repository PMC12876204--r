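# Signal conditioning: denoising, windowing, label filtering, normalization.
#
# The conditioning order is fixed: Butterworth low-pass first, then
# Savitzky-Golay smoothing, then sliding-window segmentation, then
# label-consistency filtering, then z-scoring with statistics fitted on
# training data only.

#' Construct a labeled tri-axial time series
#'
#' The elementary container passed through the preprocessing pipeline:
#' an `L x D` sample matrix, a label per timestep (or a single label for
#' the whole record) and a sampling rate.
#'
#' @param samples Numeric matrix, one row per timestep.
#' @param labels Character/factor vector of length `nrow(samples)` or 1.
#' @param fs Sampling rate in Hz.
#' @param id Optional session identifier.
#' @return An object of class `imu_series`.
#' @export
imu_series <- function(samples, labels, fs, id = "session") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  labels <- as.character(labels)
  if (length(labels) != 1L && length(labels) != nrow(samples)) {
    stopf(
      "imu_series(): %d labels for %d samples (need 1 or one per timestep)",
      length(labels), nrow(samples)
    )
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stopf("imu_series(): fs must be a positive scalar")
  }
  structure(
    list(samples = samples, labels = labels, fs = fs, id = as.character(id)),
    class = "imu_series"
  )
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf(
    "<imu_series '%s'> %d samples x %d channels @ %g Hz, %s\n",
    x$id, nrow(x$samples), ncol(x$samples), x$fs,
    if (length(x$labels) == 1L) {
      sprintf("record label '%s'", x$labels)
    } else {
      sprintf("%d distinct per-timestep labels", length(unique(x$labels)))
    }
  ))
  invisible(x)
}

# Steady-state initial filter state (transposed direct form II) for a unit
# constant input; scaled by the first sample before filtering so constant
# signals pass through an IIR filter with no start-up transient.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1L]
  a <- a / a[1L]
  if (n == 1L) {
    return(numeric(0))
  }
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  rhs <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp), rhs)
}

# One-directional IIR filter (transposed direct form II) with initial state.
iir_filter <- function(b, a, x, zi) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  b <- b / a[1L]
  a <- a / a[1L]
  z <- as.numeric(zi)
  bt <- b[-1L]
  at <- a[-1L]
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    z <- bt * xi + c(z[-1L], 0) - at * yi
    y[i] <- yi
  }
  y
}

filtfilt_one <- function(b, a, x, pad) {
  L <- length(x)
  zi <- lfilter_zi(b, a)
  ext <- c(
    2 * x[1L] - x[(pad + 1L):2L],
    x,
    2 * x[L] - x[(L - 1L):(L - pad)]
  )
  pass <- function(v) iir_filter(b, a, v, zi * v[1L])
  fb <- rev(pass(rev(pass(ext))))
  bf <- pass(rev(pass(rev(ext))))
  # averaging the forward-backward and backward-forward passes makes the
  # zero-phase output exactly symmetric under time reversal
  y <- (fb + bf) / 2
  y[(pad + 1L):(pad + L)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward over each
#' column so the net phase shift is zero.  The signal is extended at both
#' ends by odd reflection over `3 * (order + 1)` samples, and each pass is
#' initialized at its steady state for the first sample, so constant
#' signals pass through unchanged.  The two pass orders (forward-backward
#' and backward-forward) are averaged, which makes the filter exactly
#' equivariant under time reversal.
#'
#' @param x Numeric vector or `L x D` matrix (columns filtered
#'   independently).
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 2.5, below the dominant
#'   frequency band of human motion).
#' @param order Filter order (default 4).
#' @return Filtered data with the shape of `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 2.5, order = 4) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stopf("lowpass_filter(): cutoff must lie in (0, fs/2) = (0, %g)", fs / 2)
  }
  pad <- 3L * (order + 1L)
  if (nrow(x) <= pad) {
    stopf(
      "lowpass_filter(): series of length %d is too short for the %d-sample reflection padding",
      nrow(x), pad
    )
  }
  bw <- signal::butter(order, 2 * cutoff / fs, type = "low")
  out <- apply(x, 2L, function(col) filtfilt_one(bw$b, bw$a, col, pad))
  if (vec) as.numeric(out) else out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing applied per column.  With the
#' default window of 11 and polynomial order 3 the filter reproduces any
#' cubic signal exactly (edges included, which are handled by evaluating
#' the same local fit at edge offsets) while attenuating high-frequency
#' noise.
#'
#' @param x Numeric vector or `L x D` matrix.
#' @param window Odd window length (default 11).
#' @param polyorder Polynomial order, `< window` (default 3).
#' @return Smoothed data with the shape of `x`.
#' @export
savgol_smooth <- function(x, window = 11, polyorder = 3) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (window %% 2 != 1) {
    stopf("savgol_smooth(): window must be odd")
  }
  if (polyorder >= window) {
    stopf("savgol_smooth(): polyorder must be smaller than window")
  }
  if (nrow(x) < window) {
    stopf("savgol_smooth(): series shorter than the smoothing window")
  }
  out <- apply(x, 2L, signal::sgolayfilt, p = polyorder, n = window)
  if (vec) as.numeric(out) else out
}

#' Denoise a series: low-pass filtering then Savitzky-Golay smoothing
#'
#' @param series An [imu_series()].
#' @inheritParams lowpass_filter
#' @inheritParams savgol_smooth
#' @param filter Set to `FALSE` to skip denoising entirely (the
#'   no-filter ablation).
#' @return The series with denoised samples.
#' @export
denoise_series <- function(series, cutoff = 2.5, order = 4,
                           window = 11, polyorder = 3, filter = TRUE) {
  stopifnot(inherits(series, "imu_series"))
  if (!filter) {
    return(series)
  }
  s <- lowpass_filter(series$samples, series$fs, cutoff = cutoff, order = order)
  series$samples <- savgol_smooth(s, window = window, polyorder = polyorder)
  series
}

#' Segment a series into overlapping fixed-length windows
#'
#' Windows are 0-based and half-open: window `i` covers timesteps
#' `[start_i, start_i + size)` with `start_i = i * stride`.  A trailing
#' remainder shorter than `size` is dropped, so the window count is
#' `floor((L - size) / stride) + 1` when `L >= size` and 0 otherwise.
#'
#' @param series An [imu_series()].
#' @param size Window length in timesteps (default 200).
#' @param stride Hop between window starts (default 100).
#' @return A tibble with columns `session`, `start` (0-based), `window`
#'   (list of `size x D` matrices) and `labels` (list of per-timestep
#'   label slices).
#' @export
segment_windows <- function(series, size = 200, stride = 100) {
  stopifnot(inherits(series, "imu_series"))
  if (size <= 0 || stride <= 0) {
    stopf("segment_windows(): size and stride must be positive")
  }
  L <- nrow(series$samples)
  if (L < size) {
    return(tibble::tibble(
      session = character(0), start = integer(0),
      window = list(), labels = list()
    ))
  }
  starts <- seq.int(0L, L - size, by = stride)
  labs <- if (length(series$labels) == 1L) {
    rep(series$labels, L)
  } else {
    series$labels
  }
  tibble::tibble(
    session = series$id,
    start = as.integer(starts),
    window = lapply(starts, function(s) series$samples[(s + 1L):(s + size), , drop = FALSE]),
    labels = lapply(starts, function(s) labs[(s + 1L):(s + size)])
  )
}

#' Keep only windows with a single activity label
#'
#' Windows that straddle an activity transition are discarded; each
#' retained window is assigned its (unique) label.
#'
#' @param segmented A tibble from [segment_windows()] (possibly several
#'   sessions row-bound together).
#' @return The retained rows with the list-column `labels` replaced by a
#'   character column `label`.
#' @export
enforce_label_consistency <- function(segmented) {
  if (nrow(segmented) == 0L) {
    segmented$label <- character(0)
    segmented$labels <- NULL
    return(segmented)
  }
  keep <- vapply(segmented$labels, function(l) length(unique(l)) == 1L, logical(1))
  out <- segmented[keep, , drop = FALSE]
  out$label <- vapply(out$labels, function(l) l[[1L]], character(1))
  out$labels <- NULL
  out
}

#' Fit per-axis normalization statistics
#'
#' Mean and standard deviation per channel over all timesteps of the
#' supplied (training) windows.  Fit these on training folds only and
#' apply them to held-out data with [apply_normalizer()]; a constant axis
#' is clamped to a standard deviation of `eps` with a warning.
#'
#' @param windows A list of `T x D` matrices, or a 3-D array `(T, D, N)`.
#' @param eps Lower clamp for the standard deviation.
#' @return An object of class `imu_norm_stats` with fields `mean` and `sd`.
#' @export
fit_normalizer <- function(windows, eps = 1e-8) {
  x <- windows_to_array(windows)
  if (dim(x)[3L] < 2L) {
    stopf("fit_normalizer(): need at least 2 windows")
  }
  d <- dim(x)
  flat <- matrix(aperm(x, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
  mu <- colMeans(flat)
  sd <- sqrt(colMeans(flat^2) - mu^2)
  if (any(sd < eps)) {
    warnf(
      "fit_normalizer(): %d constant axis/axes; standard deviation clamped to %g",
      sum(sd < eps), eps
    )
    sd <- pmax(sd, eps)
  }
  structure(list(mean = mu, sd = sd), class = "imu_norm_stats")
}

#' Apply fitted normalization statistics
#'
#' @param stats An `imu_norm_stats` from [fit_normalizer()].
#' @param windows A list of `T x D` matrices or a 3-D array `(T, D, N)`.
#' @return Normalized windows in the same container shape as the input.
#' @export
apply_normalizer <- function(stats, windows) {
  stopifnot(inherits(stats, "imu_norm_stats"))
  if (is.array(windows) && length(dim(windows)) == 3L) {
    out <- windows
    for (j in seq_len(dim(windows)[2L])) {
      out[, j, ] <- (windows[, j, ] - stats$mean[j]) / stats$sd[j]
    }
    return(out)
  }
  lapply(windows, function(w) {
    sweep(sweep(w, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  })
}

#' Encode activity labels as dense integer class ids
#'
#' Classes are ordered lexicographically so that the mapping is
#' deterministic across runs; ids run from 0 to K-1.
#'
#' @param labels Character vector of observed labels.
#' @param map Optional existing `imu_label_map` to reuse (transform mode);
#'   labels absent from the map are an error.
#' @return A list with `ids` (integer vector) and `map`
#'   (an `imu_label_map`: tibble with columns `class`, `id`).
#' @export
encode_labels <- function(labels, map = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    stopf("encode_labels(): empty label collection")
  }
  if (is.null(map)) {
    classes <- sort(unique(labels), method = "radix")
    map <- structure(
      tibble::tibble(class = classes, id = seq_along(classes) - 1L),
      class = c("imu_label_map", class(tibble::tibble()))
    )
  } else {
    stopifnot(inherits(map, "imu_label_map"))
    unseen <- setdiff(unique(labels), map$class)
    if (length(unseen) > 0L) {
      stopf("encode_labels(): unseen label(s): %s", paste(unseen, collapse = ", "))
    }
  }
  ids <- map$id[match(labels, map$class)]
  list(ids = as.integer(ids), map = map)
}

#' Decode integer class ids back to labels
#'
#' @param ids Integer class ids.
#' @param map An `imu_label_map`.
#' @export
decode_labels <- function(ids, map) {
  stopifnot(inherits(map, "imu_label_map"))
  if (any(!ids %in% map$id)) {
    stopf("decode_labels(): id outside the label map")
  }
  map$class[match(ids, map$id)]
}

# Coerce a list of T x D matrices (or a 3-D array) to a (T, D, N) array.
windows_to_array <- function(windows) {
  if (is.array(windows) && length(dim(windows)) == 3L) {
    return(windows)
  }
  stopifnot(is.list(windows), length(windows) > 0L)
  d <- dim(windows[[1L]])
  x <- array(0, c(d[1L], d[2L], length(windows)))
  for (i in seq_along(windows)) x[, , i] <- windows[[i]]
  x
}

#' Run the full conditioning pipeline over a collection of sessions
#'
#' Denoises each session (unless `filter = FALSE`), segments it into
#' overlapping windows, keeps label-consistent windows and encodes labels.
#' Normalization is *not* applied here: statistics must be fitted on
#' training folds only (see [fit_normalizer()]), which the training
#' harness does per fold.
#'
#' @param sessions A list of [imu_series()] objects.
#' @param size,stride Window geometry (defaults 200 / 100).
#' @param filter Apply denoising (default `TRUE`).
#' @param cutoff,order,window,polyorder Denoising parameters, see
#'   [denoise_series()].
#' @param label_map Optional fixed `imu_label_map`.
#' @return An object of class `har_windows`: a list with `x` (array
#'   `(T, D, N)`), `label_id` (0-based integer vector), `label_map`,
#'   `sources` (tibble with `session`, `start`, `label`), `fs`, `size`,
#'   `stride`, `filtered`.
#' @export
preprocess_sessions <- function(sessions, size = 200, stride = 100,
                                filter = TRUE, cutoff = 2.5, order = 4,
                                window = 11, polyorder = 3,
                                label_map = NULL) {
  stopifnot(is.list(sessions), length(sessions) > 0L)
  fs <- sessions[[1L]]$fs
  segs <- lapply(sessions, function(s) {
    s <- denoise_series(s,
      cutoff = cutoff, order = order, window = window,
      polyorder = polyorder, filter = filter
    )
    segment_windows(s, size = size, stride = stride)
  })
  seg <- dplyr::bind_rows(segs)
  seg <- enforce_label_consistency(seg)
  if (nrow(seg) == 0L) {
    stopf("preprocess_sessions(): no label-consistent windows produced")
  }
  enc <- encode_labels(seg$label, map = label_map)
  structure(
    list(
      x = windows_to_array(seg$window),
      label_id = enc$ids,
      label_map = enc$map,
      sources = tibble::tibble(
        session = seg$session, start = seg$start, label = seg$label
      ),
      fs = fs, size = size, stride = stride, filtered = filter
    ),
    class = "har_windows"
  )
}

#' @export
print.har_windows <- function(x, ...) {
  cat(sprintf(
    "<har_windows> %d windows of %d x %d @ %g Hz, %d classes%s\n",
    dim(x$x)[3L], dim(x$x)[1L], dim(x$x)[2L], x$fs, nrow(x$label_map),
    if (x$filtered) "" else " (denoising skipped)"
  ))
  print(dplyr::count(x$sources, .data$label))
  invisible(x)
}
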