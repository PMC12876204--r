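# Binary frame protocol for JY61-family inertial sensors.
#
# Each physical sample is transmitted as three consecutive 11-byte frames:
# an acceleration frame, an angular-velocity frame and an attitude-angle
# frame.  A frame is
#
#   0x55 | type | 8 payload bytes | checksum
#
# with type 0x51 (acceleration), 0x52 (angular velocity) or 0x53 (angle).
# The payload holds four little-endian signed shorts: the three axis values
# followed by the chip temperature.  The checksum is the low byte of the sum
# of all ten preceding bytes.  Ten consecutive samples are aggregated into
# one transmission packet, so a 100 Hz sample stream is sent as 10 packets
# per second.

FRAME_HEADER <- 0x55L
FRAME_TYPES <- c(accel = 0x51L, gyro = 0x52L, angle = 0x53L)
FRAME_BYTES <- 11L
SAMPLE_BYTES <- 3L * FRAME_BYTES

# Full-scale ranges used by the range-based raw-to-physical conversion
# (value = raw / 32768 * full_scale).
FULL_SCALE <- c(accel = 16, gyro = 2000, angle = 180)

# Datasheet sensitivities (LSB per physical unit).  Note these are the
# sensor's register-level figures and are mutually inconsistent with the
# transmitted full-scale ranges above for a 16-bit word; they are kept only
# so that resolution figures quoted from the datasheet can be reproduced.
# See sensor_resolution().
DATASHEET_SENSITIVITY <- c(accel = 16384, gyro = 131)

FRAME_COLUMNS <- c(
  "index", "ax", "ay", "az", "gx", "gy", "gz",
  "roll", "pitch", "yaw", "temp"
)

#' Combine a little-endian byte pair into a signed 16-bit integer
#'
#' Sensor words are transmitted low byte first; the pair `(low, high)`
#' represents the two's-complement integer `(high << 8) | low`.
#'
#' @param low,high Integer vectors of byte values in `[0, 255]`.
#' @return Integer vector in `[-32768, 32767]`.
#' @examples
#' decode_int16(0x00, 0x80) # -32768
#' decode_int16(0xFF, 0x7F) # 32767
#' @export
decode_int16 <- function(low, high) {
  low <- as.integer(low)
  high <- as.integer(high)
  if (anyNA(low) || anyNA(high) || any(low < 0L | low > 255L) ||
      any(high < 0L | high > 255L)) {
    stopf("decode_int16(): byte values must lie in [0, 255]")
  }
  u <- high * 256L + low
  ifelse(u >= 32768L, u - 65536L, u)
}

encode_int16 <- function(value) {
  value <- as.integer(round(value))
  if (any(value < -32768L | value > 32767L)) {
    stopf("encode_int16(): value outside the signed 16-bit range")
  }
  u <- ifelse(value < 0L, value + 65536L, value)
  list(low = u %% 256L, high = u %/% 256L)
}

#' Convert a raw sensor word to physical units
#'
#' Uses the range-based convention `raw / 32768 * full_scale` with full
#' scales of 16 g (acceleration), 2000 deg/s (angular velocity) and
#' 180 deg (attitude angle).
#'
#' @param raw Integer vector in `[-32768, 32767]`.
#' @param kind One of `"accel"`, `"gyro"`, `"angle"`.
#' @return Numeric vector in g, deg/s or deg.
#' @seealso [sensor_resolution()] for the per-LSB step sizes.
#' @export
raw_to_physical <- function(raw, kind = c("accel", "gyro", "angle")) {
  kind <- match.arg(kind)
  if (any(raw < -32768 | raw > 32767)) {
    stopf("raw_to_physical(): raw value outside the signed 16-bit range")
  }
  raw / 32768 * FULL_SCALE[[kind]]
}

physical_to_raw <- function(value, kind = c("accel", "gyro", "angle")) {
  kind <- match.arg(kind)
  fs <- FULL_SCALE[[kind]]
  if (any(abs(value) > fs)) {
    stopf("physical_to_raw(): |value| exceeds the %s full scale of %g", kind, fs)
  }
  pmin(pmax(round(value / fs * 32768), -32768), 32767)
}

#' Per-LSB resolution of a sensor channel
#'
#' Two conventions coexist in sensor documentation. The transmission
#' protocol is range-based: one LSB equals `full_scale / 32768` (e.g.
#' 2000/32768 deg/s for the gyroscope).  Datasheets instead quote a
#' register sensitivity in LSB per unit, whose reciprocal (1/16384 g,
#' 1/131 deg/s) does not correspond to the transmitted 16-bit full-scale
#' word; both figures are exposed here so either can be quoted.
#'
#' @param kind `"accel"` or `"gyro"` (plus `"angle"` for `method = "range"`).
#' @param method `"range"` (full scale / 32768) or `"sensitivity"`
#'   (reciprocal datasheet sensitivity).
#' @return Resolution in physical units per LSB.
#' @examples
#' sensor_resolution("accel", "sensitivity") # ~6.1e-5 g
#' sensor_resolution("gyro", "sensitivity")  # ~7.6e-3 deg/s
#' @export
sensor_resolution <- function(kind = c("accel", "gyro", "angle"),
                              method = c("range", "sensitivity")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (method == "range") {
    FULL_SCALE[[kind]] / 32768
  } else {
    if (!kind %in% names(DATASHEET_SENSITIVITY)) {
      stopf("sensor_resolution(): no datasheet sensitivity for kind '%s'", kind)
    }
    1 / DATASHEET_SENSITIVITY[[kind]]
  }
}

frame_checksum <- function(bytes10) {
  as.integer(sum(as.integer(bytes10)) %% 256L)
}

encode_one_frame <- function(type_byte, values_raw, temp_raw) {
  lohi <- encode_int16(c(values_raw, temp_raw))
  payload <- as.integer(rbind(lohi$low, lohi$high))
  body <- c(FRAME_HEADER, type_byte, payload)
  as.raw(c(body, frame_checksum(body)))
}

#' Encode one decoded sample as three binary frames
#'
#' The inverse of [parse_stream()] for a single sample: physical values are
#' quantized to signed shorts (round to nearest, so the decode error is at
#' most half an LSB of the channel scale) and packed into an acceleration,
#' an angular-velocity and an angle frame.
#'
#' @param triple A list or one-row data frame with `ax, ay, az` (g),
#'   `gx, gy, gz` (deg/s), `roll, pitch, yaw` (deg) and optionally
#'   `temp` (Celsius, default 0).
#' @return A [raw] vector of 33 bytes.
#' @export
encode_frame <- function(triple) {
  need <- setdiff(FRAME_COLUMNS, c("index", "temp"))
  if (!all(need %in% names(triple))) {
    stopf(
      "encode_frame(): missing fields: %s",
      paste(setdiff(need, names(triple)), collapse = ", ")
    )
  }
  temp <- triple$temp %||% 0
  c(
    encode_one_frame(
      FRAME_TYPES[["accel"]],
      physical_to_raw(c(triple$ax, triple$ay, triple$az), "accel"),
      round(temp * 100)
    ),
    encode_one_frame(
      FRAME_TYPES[["gyro"]],
      physical_to_raw(c(triple$gx, triple$gy, triple$gz), "gyro"),
      round(temp * 100)
    ),
    encode_one_frame(
      FRAME_TYPES[["angle"]],
      physical_to_raw(c(triple$roll, triple$pitch, triple$yaw), "angle"),
      round(temp * 100)
    )
  )
}

#' Encode a table of decoded samples as a binary stream
#'
#' @param frames A data frame in the [frames_to_table()] layout.
#' @return A [raw] vector of `33 * nrow(frames)` bytes.
#' @export
encode_frames <- function(frames) {
  frames <- as.data.frame(frames)
  if (nrow(frames) == 0L) {
    return(raw(0))
  }
  do.call(c, lapply(seq_len(nrow(frames)), function(i) {
    encode_frame(frames[i, , drop = FALSE])
  }))
}

#' Decode a binary sensor stream into a sample table
#'
#' Scans an arbitrary byte sequence for checksum-valid frames, assembles
#' consecutive (acceleration, angular-velocity, angle) frames into decoded
#' samples, and reports corruption without raising.  After a bad byte the
#' parser resynchronizes by scanning forward for the next header byte.
#'
#' @param bytes A [raw] vector (possibly containing garbage).
#' @param validate_checksum If `FALSE`, accept frames whose checksum fails
#'   (they are still counted in the diagnostics).
#' @return A list with
#'   * `frames`: tibble with columns
#'     `index, ax, ay, az, gx, gy, gz, roll, pitch, yaw, temp`
#'     (index is a 0-based sample counter);
#'   * `diagnostics`: list with `n_samples`, `n_frames_valid`,
#'     `n_checksum_failures`, `n_bytes_skipped`, `n_incomplete_frames`
#'     (frames that never formed a complete sample, including a trailing
#'     truncated frame).
#' @export
parse_stream <- function(bytes, validate_checksum = TRUE) {
  stopifnot(is.raw(bytes))
  b <- as.integer(bytes)
  n <- length(b)
  pos <- 1L
  skipped <- 0L
  checksum_fail <- 0L
  valid <- 0L
  pend <- list(accel = NULL, gyro = NULL, angle = NULL)
  pending_frames <- 0L
  incomplete <- 0L
  rows <- vector("list", n %/% SAMPLE_BYTES + 1L)
  nrow_out <- 0L

  flush_pending <- function() {
    incomplete <<- incomplete + pending_frames
    pend <<- list(accel = NULL, gyro = NULL, angle = NULL)
    pending_frames <<- 0L
  }

  while (pos + FRAME_BYTES - 1L <= n) {
    if (b[pos] != FRAME_HEADER) {
      pos <- pos + 1L
      skipped <- skipped + 1L
      next
    }
    type <- b[pos + 1L]
    kind <- names(FRAME_TYPES)[match(type, FRAME_TYPES)]
    if (is.na(kind)) {
      pos <- pos + 1L
      skipped <- skipped + 1L
      next
    }
    frame <- b[pos:(pos + FRAME_BYTES - 1L)]
    ok <- frame[FRAME_BYTES] == frame_checksum(frame[1:(FRAME_BYTES - 1L)])
    if (!ok) {
      checksum_fail <- checksum_fail + 1L
      if (validate_checksum) {
        # treat as corruption: resynchronize from the next byte
        pos <- pos + 1L
        skipped <- skipped + 1L
        next
      }
    }
    payload <- frame[3:10]
    words <- decode_int16(payload[c(1L, 3L, 5L, 7L)], payload[c(2L, 4L, 6L, 8L)])
    if (kind == "accel" && pending_frames > 0L) flush_pending()
    if (!is.null(pend[[kind]])) flush_pending()
    pend[[kind]] <- words
    pending_frames <- pending_frames + 1L
    valid <- valid + 1L
    if (!is.null(pend$accel) && !is.null(pend$gyro) && !is.null(pend$angle)) {
      a <- raw_to_physical(pend$accel[1:3], "accel")
      g <- raw_to_physical(pend$gyro[1:3], "gyro")
      an <- raw_to_physical(pend$angle[1:3], "angle")
      nrow_out <- nrow_out + 1L
      rows[[nrow_out]] <- c(a, g, an, pend$angle[4L] / 100)
      pend <- list(accel = NULL, gyro = NULL, angle = NULL)
      pending_frames <- 0L
    }
    pos <- pos + FRAME_BYTES
  }
  if (pos <= n) {
    # trailing bytes too short to hold a frame
    if (b[pos] == FRAME_HEADER && !is.na(match(b[min(pos + 1L, n)], FRAME_TYPES))) {
      incomplete <- incomplete + 1L
    } else {
      skipped <- skipped + (n - pos + 1L)
    }
  }
  flush_pending()

  if (nrow_out == 0L) {
    frames <- empty_frame_table()
  } else {
    m <- do.call(rbind, rows[seq_len(nrow_out)])
    frames <- tibble::as_tibble(as.data.frame(m))
    names(frames) <- FRAME_COLUMNS[-1L]
    frames <- tibble::add_column(frames, index = seq_len(nrow_out) - 1L, .before = 1L)
  }
  list(
    frames = frames,
    diagnostics = list(
      n_samples = nrow_out,
      n_frames_valid = valid,
      n_checksum_failures = checksum_fail,
      n_bytes_skipped = skipped,
      n_incomplete_frames = incomplete
    )
  )
}

empty_frame_table <- function() {
  out <- as.list(c(list(integer(0)), rep(list(numeric(0)), 10L)))
  names(out) <- FRAME_COLUMNS
  tibble::as_tibble(out)
}

#' Aggregate ten consecutive samples into one transmission packet
#'
#' Firmware batches ten samples per packet, reducing a 100 Hz sample
#' stream to 10 transmitted packets per second.
#'
#' @param frames A data frame of exactly 10 rows whose `index` column
#'   increases by 1.
#' @return An object of class `imu_packet`.
#' @export
pack_frames <- function(frames) {
  frames <- tibble::as_tibble(frames)
  if (nrow(frames) != 10L) {
    stopf("pack_frames(): expected exactly 10 frames, got %d", nrow(frames))
  }
  if (!all(diff(frames$index) == 1L)) {
    stopf("pack_frames(): frame indices must increase by 1")
  }
  structure(list(frames = frames), class = "imu_packet")
}

#' @rdname pack_frames
#' @param packet An `imu_packet`.
#' @export
unpack_packet <- function(packet) {
  stopifnot(inherits(packet, "imu_packet"))
  packet$frames
}

#' Convert decoded samples to the canonical tabular layout
#'
#' @param frames A data frame holding at least the decoded channels; an
#'   `index` column is added if missing, a `temp` column defaults to 0.
#' @return A tibble with columns
#'   `index, ax, ay, az, gx, gy, gz, roll, pitch, yaw, temp`.
#' @export
frames_to_table <- function(frames) {
  frames <- tibble::as_tibble(frames)
  if (nrow(frames) == 0L) {
    return(empty_frame_table())
  }
  if (!"index" %in% names(frames)) {
    frames$index <- seq_len(nrow(frames)) - 1L
  }
  if (!"temp" %in% names(frames)) {
    frames$temp <- 0
  }
  missing <- setdiff(FRAME_COLUMNS, names(frames))
  if (length(missing) > 0L) {
    stopf("frames_to_table(): missing columns: %s", paste(missing, collapse = ", "))
  }
  frames[FRAME_COLUMNS]
}

#' Read or write the canonical sample CSV
#'
#' @param frames A frame table ([frames_to_table()] layout).
#' @param path File path.
#' @export
write_frame_csv <- function(frames, path) {
  readr::write_csv(frames_to_table(frames), path)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  frames <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  frames_to_table(frames)
}

#' Read or write a raw binary frame stream
#'
#' @param path File path of a raw byte dump.
#' @export
read_frame_stream <- function(path) {
  readBin(path, what = "raw", n = file.info(path)$size)
}

#' @rdname read_frame_stream
#' @param bytes A raw vector.
#' @export
write_frame_stream <- function(bytes, path) {
  stopifnot(is.raw(bytes))
  writeBin(bytes, path)
  invisible(path)
}
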