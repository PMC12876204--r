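# Dataset-layout adapters for tabular inertial data.
#
# Three layouts are supported:
#   generic_csv  the canonical frame table written by the codec (plus an
#                optional `label` column);
#   ucihar_raw   per-axis raw-signal text files, one pre-segmented
#                128-step window per row, labels in a companion file;
#   pamap2_dat   space-delimited .dat with timestamp, activity id, heart
#                rate and three 17-column IMU blocks; one accelerometer
#                triple is extracted by documented column indices.

# PAMAP2 column anatomy (1-based): 1 timestamp, 2 activity id, 3 heart
# rate, 4-20 hand IMU, 21-37 chest IMU, 38-54 ankle IMU.  Within an IMU
# block: temperature, 3x accel (16 g), 3x accel (6 g), 3x gyro, 3x
# magnetometer, 4x orientation.  The default accelerometer triple is the
# chest wide-range accelerometer, columns 22-24.
PAMAP2_CHEST_ACCEL <- c(22L, 23L, 24L)

#' Read tabular inertial data in a named layout
#'
#' @param path File path (for `ucihar_raw`, the path of the x-axis file;
#'   the y/z/label files are given separately).
#' @param layout One of `"generic_csv"`, `"ucihar_raw"`, `"pamap2_dat"`.
#' @param fs Sampling rate to stamp on the series (defaults: 100 for
#'   generic CSV, 50 for UCI-HAR, 100 for PAMAP2).
#' @param y_path,z_path,label_path Companion per-axis and label files
#'   (`ucihar_raw` only).
#' @param accel_cols 1-based accelerometer column indices
#'   (`pamap2_dat` only; default chest wide-range accelerometer).
#' @param max_gap Longest run of missing values repaired by linear
#'   interpolation before the series is split (`pamap2_dat`,
#'   default 10 samples).
#' @return A list of [imu_series()] objects (for `ucihar_raw`, one
#'   single-label series per record row).
#' @export
read_inertial_table <- function(path,
                                layout = c("generic_csv", "ucihar_raw", "pamap2_dat"),
                                fs = NULL,
                                y_path = NULL, z_path = NULL, label_path = NULL,
                                accel_cols = PAMAP2_CHEST_ACCEL,
                                max_gap = 10L) {
  layout <- match.arg(layout)
  switch(layout,
    generic_csv = read_generic_csv(path, fs %||% 100),
    ucihar_raw = read_ucihar_raw(path, y_path, z_path, label_path, fs %||% 50),
    pamap2_dat = read_pamap2_dat(path, fs %||% 100, accel_cols, max_gap)
  )
}

read_generic_csv <- function(path, fs) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("ax", "ay", "az")
  if (!all(need %in% names(tab))) {
    stopf("generic_csv: missing column(s): %s", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  labels <- if ("label" %in% names(tab)) tab$label else "unlabeled"
  list(imu_series(
    as.matrix(tab[need]),
    labels = labels, fs = fs,
    id = tools::file_path_sans_ext(basename(path))
  ))
}

read_axis_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (anyNA(v)) stopf("%s: malformed row at line %d", basename(path), i)
    v
  })
  n <- lengths(rows)
  if (length(unique(n)) != 1L) {
    stopf("%s: ragged rows (lengths %s)", basename(path), paste(unique(n), collapse = ", "))
  }
  do.call(rbind, rows)
}

read_ucihar_raw <- function(x_path, y_path, z_path, label_path, fs) {
  if (is.null(y_path) || is.null(z_path)) {
    stopf("ucihar_raw: y_path and z_path are required")
  }
  ax <- read_axis_file(x_path)
  ay <- read_axis_file(y_path)
  az <- read_axis_file(z_path)
  if (!all(dim(ax) == dim(ay)) || !all(dim(ax) == dim(az))) {
    stopf("ucihar_raw: axis files disagree in shape")
  }
  labels <- if (!is.null(label_path)) {
    as.character(trimws(readLines(label_path)))
  } else {
    rep("unlabeled", nrow(ax))
  }
  if (length(labels) != nrow(ax)) {
    stopf("ucihar_raw: %d labels for %d records", length(labels), nrow(ax))
  }
  lapply(seq_len(nrow(ax)), function(i) {
    imu_series(
      cbind(ax = ax[i, ], ay = ay[i, ], az = az[i, ]),
      labels = labels[i], fs = fs, id = sprintf("record_%04d", i)
    )
  })
}

# Linearly interpolate interior NA runs of length <= max_gap per column;
# returns the repaired matrix and a logical row mask of still-missing rows.
interpolate_gaps <- function(m, max_gap) {
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (!anyNA(v)) next
    na <- is.na(v)
    r <- rle(na)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      if (r$lengths[i] <= max_gap && starts[i] > 1L && ends[i] < length(v)) {
        lo <- starts[i] - 1L
        hi <- ends[i] + 1L
        v[starts[i]:ends[i]] <- stats::approx(
          x = c(lo, hi), y = v[c(lo, hi)], xout = starts[i]:ends[i]
        )$y
      }
    }
    m[, j] <- v
  }
  m
}

read_pamap2_dat <- function(path, fs, accel_cols, max_gap) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    v
  })
  n <- lengths(rows)
  if (any(n < max(accel_cols))) {
    stopf(
      "pamap2_dat: line %d has %d fields, need at least %d",
      which(n < max(accel_cols))[1L], min(n), max(accel_cols)
    )
  }
  m <- do.call(rbind, rows)
  activity <- m[, 2L]
  if (anyNA(activity)) {
    stopf("pamap2_dat: malformed activity id at line %d", which(is.na(activity))[1L])
  }
  acc <- interpolate_gaps(m[, accel_cols, drop = FALSE], max_gap)
  keep <- activity != 0 & !apply(acc, 1L, anyNA)
  # split into contiguous runs of retained rows (id-0 spans and
  # unrepairable gaps break the series)
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    out[[length(out) + 1L]] <- imu_series(
      acc[idx, , drop = FALSE],
      labels = as.character(activity[idx]),
      fs = fs,
      id = sprintf("%s_seg%02d", tools::file_path_sans_ext(basename(path)), length(out) + 1L)
    )
  }
  out
}

#' Linearly resample fixed-length records to a target window length
#'
#' Pre-segmented benchmark records (e.g. 128-step windows at 50 Hz) are
#' adapted to the model's window length by per-axis linear resampling.
#'
#' @param series An [imu_series()] (single-label record).
#' @param size Target length.
#' @return The resampled series.
#' @export
resample_record <- function(series, size = 200) {
  stopifnot(inherits(series, "imu_series"))
  L <- nrow(series$samples)
  xout <- seq(1, L, length.out = size)
  series$samples <- apply(series$samples, 2L, function(col) {
    stats::approx(seq_len(L), col, xout = xout)$y
  })
  if (length(series$labels) != 1L) {
    stopf("resample_record(): only single-label records can be resampled")
  }
  series
}
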