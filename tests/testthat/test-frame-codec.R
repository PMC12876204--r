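# Binary frame protocol: byte-pair decoding, physical scaling, stream
# parsing with corruption recovery, packet aggregation, tabular export.

test_that("decode_int16 matches a two's-complement reference over all byte pairs", {
  lo <- rep(0:255, times = 256)
  hi <- rep(0:255, each = 256)
  got <- decode_int16(lo, hi)
  u <- hi * 256 + lo
  ref <- as.integer(ifelse(u >= 32768, u - 65536, u)) # reference two's-complement table
  expect_identical(got, ref)
  expect_identical(decode_int16(0x00, 0x00), 0L)
  expect_identical(decode_int16(0x00, 0x80), -32768L)
  expect_identical(decode_int16(0xFF, 0x7F), 32767L)
  expect_error(decode_int16(-1, 0), "0, 255")
  expect_error(decode_int16(0, 256), "0, 255")
})

test_that("raw_to_physical applies range-based scaling and is odd", {
  expect_equal(raw_to_physical(0, "accel"), 0)
  expect_equal(raw_to_physical(16384, "accel"), 8)
  expect_equal(raw_to_physical(-32768, "gyro"), -2000)
  expect_equal(raw_to_physical(-32768, "angle"), -180)
  set.seed(1)
  r <- sample(-32767:32767, 500)
  for (kind in c("accel", "gyro", "angle")) {
    expect_equal(raw_to_physical(-r, kind), -raw_to_physical(r, kind))
  }
  expect_error(raw_to_physical(40000, "accel"), "16-bit")
})

test_that("sensor resolutions reproduce both the protocol and datasheet figures", {
  expect_equal(sensor_resolution("gyro", "range"), 2000 / 32768)
  # datasheet sensitivities quoted to two significant figures
  expect_equal(signif(sensor_resolution("accel", "sensitivity"), 2), 6.1e-5)
  expect_equal(signif(sensor_resolution("gyro", "sensitivity"), 2), 7.6e-3)
  expect_error(sensor_resolution("angle", "sensitivity"), "sensitivity")
})

test_that("encode_frame produces valid frames with the documented layout", {
  zero <- list(
    ax = 0, ay = 0, az = 0, gx = 0, gy = 0, gz = 0,
    roll = 0, pitch = 0, yaw = 0, temp = 0
  )
  bytes <- encode_frame(zero)
  expect_length(bytes, 33)
  expect_identical(as.integer(bytes[c(1, 12, 23)]), rep(0x55L, 3))
  expect_identical(as.integer(bytes[c(2, 13, 24)]), c(0x51L, 0x52L, 0x53L))
  expect_true(all(as.integer(bytes[3:10]) == 0))
  # checksum of the all-zero acceleration frame: 0x55 + 0x51
  expect_identical(as.integer(bytes[11]), as.integer((0x55 + 0x51) %% 256))

  eight_g <- utils::modifyList(zero, list(ax = 8))
  b <- encode_frame(eight_g)
  expect_identical(as.integer(b[3:4]), c(0x00L, 0x40L)) # 16384 little-endian
  expect_error(encode_frame(utils::modifyList(zero, list(ax = 17))), "full scale")
})

test_that("parse_stream round-trips encoded triples and reports corruption", {
  empty <- parse_stream(raw(0))
  expect_identical(nrow(empty$frames), 0L)
  expect_identical(empty$diagnostics$n_bytes_skipped, 0L)

  tr <- random_triple(7)
  bytes <- encode_frame(tr)
  out <- parse_stream(bytes)
  expect_identical(nrow(out$frames), 1L)
  half_lsb <- c(rep(16, 3), rep(2000, 3), rep(180, 3)) / 32768 / 2
  got <- as.numeric(out$frames[1, c("ax", "ay", "az", "gx", "gy", "gz", "roll", "pitch", "yaw")])
  want <- as.numeric(unlist(tr[c("ax", "ay", "az", "gx", "gy", "gz", "roll", "pitch", "yaw")]))
  expect_true(all(abs(got - want) <= half_lsb + 1e-12))
  expect_equal(out$frames$temp[1], tr$temp, tolerance = 0.01)

  # flip one payload byte: the damaged frame fails its checksum, the
  # remaining two frames are orphaned (incomplete sample)
  bad <- bytes
  bad[5] <- xor(bad[5], as.raw(0x10))
  out2 <- parse_stream(bad)
  expect_identical(nrow(out2$frames), 0L)
  expect_identical(out2$diagnostics$n_checksum_failures, 1L)
  expect_identical(out2$diagnostics$n_incomplete_frames, 2L)

  # garbage prefix: parser resynchronizes on the next header byte
  out3 <- parse_stream(c(as.raw(c(1, 2, 3)), bytes))
  expect_identical(nrow(out3$frames), 1L)
  expect_identical(out3$diagnostics$n_bytes_skipped, 3L)
})

test_that("encode/parse round-trip stays within half an LSB over many triples", {
  set.seed(42)
  n <- 200L
  tab <- tibble::tibble(
    index = seq_len(n) - 1L,
    ax = runif(n, -15.9, 15.9), ay = runif(n, -15.9, 15.9), az = runif(n, -15.9, 15.9),
    gx = runif(n, -1999, 1999), gy = runif(n, -1999, 1999), gz = runif(n, -1999, 1999),
    roll = runif(n, -179, 179), pitch = runif(n, -179, 179), yaw = runif(n, -179, 179),
    temp = runif(n, -10, 60)
  )
  out <- parse_stream(encode_frames(tab))
  expect_identical(nrow(out$frames), n)
  expect_identical(out$diagnostics$n_checksum_failures, 0L)
  for (col in c("ax", "ay", "az")) {
    expect_lt(max(abs(out$frames[[col]] - tab[[col]])), 16 / 32768 / 2 + 1e-12)
  }
  for (col in c("gx", "gy", "gz")) {
    expect_lt(max(abs(out$frames[[col]] - tab[[col]])), 2000 / 32768 / 2 + 1e-12)
  }
  for (col in c("roll", "pitch", "yaw")) {
    expect_lt(max(abs(out$frames[[col]] - tab[[col]])), 180 / 32768 / 2 + 1e-12)
  }
})

test_that("packet aggregation batches exactly ten frames and inverts", {
  out <- parse_stream(encode_frames(frames_to_table(tibble::tibble(
    ax = seq(0.1, 1, by = 0.1), ay = 0, az = 0, gx = 0, gy = 0, gz = 0,
    roll = 0, pitch = 0, yaw = 0
  ))))
  pkt <- pack_frames(out$frames)
  expect_identical(unpack_packet(pkt), out$frames)
  expect_error(pack_frames(out$frames[1:9, ]), "10 frames")

  # one second of 100 Hz samples aggregates into 10 packets
  sec <- frames_to_table(tibble::tibble(
    ax = rep(0, 100), ay = 0, az = 0, gx = 0, gy = 0, gz = 0,
    roll = 0, pitch = 0, yaw = 0
  ))
  packets <- lapply(split(seq_len(100), ceiling(seq_len(100) / 10)), function(i) {
    pack_frames(sec[i, ])
  })
  expect_length(packets, 10)
})

test_that("frames_to_table writes and reads CSV losslessly with stable header", {
  set.seed(3)
  tab <- frames_to_table(tibble::tibble(
    ax = rnorm(100), ay = rnorm(100), az = rnorm(100),
    gx = rnorm(100), gy = rnorm(100), gz = rnorm(100),
    roll = rnorm(100), pitch = rnorm(100), yaw = rnorm(100)
  ))
  expect_identical(
    names(tab),
    c("index", "ax", "ay", "az", "gx", "gy", "gz", "roll", "pitch", "yaw", "temp")
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_frame_csv(tab, f)
  back <- read_frame_csv(f)
  expect_identical(names(back), names(tab))
  expect_lt(max(abs(as.matrix(back[-1]) - as.matrix(tab[-1]))), 1e-6)
  # header is byte-identical across writes
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_frame_csv(tab, f2)
  expect_identical(readLines(f)[1], readLines(f2)[1])
  # empty input: header-only table
  expect_identical(nrow(frames_to_table(tibble::tibble())), 0L)
})
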