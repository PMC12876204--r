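# Signal conditioning: zero-phase low-pass filtering, Savitzky-Golay
# smoothing, windowing, label filtering, normalization, label encoding.

test_that("low-pass filter passes DC, attenuates per the Butterworth response, and is zero-phase", {
  fs <- 20
  L <- 400
  t <- seq_len(L) / fs

  # DC gain 1: constant columns pass through unchanged
  x <- matrix(3.7, L, 2)
  expect_equal(lowpass_filter(x, fs), x, tolerance = 1e-10)

  # closed-form 4th-order Butterworth magnitude at f/cutoff, squared for
  # the two passes
  f_hi <- 0.9 * fs / 2
  s <- sin(2 * pi * f_hi * t)
  y <- lowpass_filter(s, fs, cutoff = 2.5)
  gain2 <- (1 / sqrt(1 + (f_hi / 2.5)^(2 * 4)))^2
  mid <- 50:350 # away from the boundaries
  expect_lt(sqrt(mean(y[mid]^2)) / sqrt(mean(s[mid]^2)), 0.05)
  expect_lt(sqrt(mean(y[mid]^2)) / sqrt(mean(s[mid]^2)), 10 * gain2 + 1e-3)

  # exact time-reversal equivariance
  set.seed(9)
  z <- rnorm(L)
  expect_equal(lowpass_filter(rev(z), fs), rev(lowpass_filter(z, fs)),
    tolerance = 1e-8
  )

  expect_error(lowpass_filter(z, fs, cutoff = 10), "Nyquist|cutoff")
  expect_error(lowpass_filter(z[1:10], fs), "too short")
})

test_that("Savitzky-Golay smoothing is exact on cubics and reduces noise variance", {
  t <- seq(-1, 1, length.out = 101)
  cubic <- 2 + t - 3 * t^2 + 0.5 * t^3
  sm <- savgol_smooth(cubic)
  expect_lt(max(abs(sm - cubic)), 1e-9) # includes the edges

  const <- rep(4.2, 60)
  expect_equal(savgol_smooth(const), const, tolerance = 1e-12)

  set.seed(4)
  noise <- rnorm(500)
  expect_lt(var(savgol_smooth(noise)), var(noise))

  # direct convolution with the reference central kernel on the interior
  ref_kernel <- signal::sgolay(p = 3, n = 11)[6, ]
  conv <- stats::filter(noise, rev(ref_kernel), sides = 2)
  sm2 <- savgol_smooth(noise)
  expect_equal(sm2[20:480], as.numeric(conv[20:480]), tolerance = 1e-10)

  expect_error(savgol_smooth(noise, window = 10), "odd")
  expect_error(savgol_smooth(noise, window = 11, polyorder = 11), "smaller")
})

test_that("window segmentation matches the closed-form count and brute force", {
  mk <- function(L) imu_series(matrix(rnorm(L * 3), L, 3), rep("a", L), fs = 20)
  expect_identical(nrow(segment_windows(mk(400), 200, 100)), 3L)
  expect_identical(segment_windows(mk(400), 200, 100)$start, c(0L, 100L, 200L))
  expect_identical(nrow(segment_windows(mk(199), 200, 100)), 0L)

  # property sweep vs brute-force enumeration of valid starts
  for (L in c(200, 250, 1000, 517)) {
    for (Tn in c(64, 200)) {
      for (stride in c(13, 100, 200)) {
        got <- nrow(segment_windows(mk(L), Tn, stride))
        brute <- sum(sapply(seq.int(0, max(L - 1, 0)), function(s) s %% stride == 0 && s + Tn <= L))
        expect_identical(got, as.integer(brute))
      }
    }
  }

  # windows are half-open slices of the source
  s <- mk(450)
  seg <- segment_windows(s, 200, 100)
  expect_equal(seg$window[[3]], s$samples[201:400, ])
})

test_that("label-consistency filtering drops exactly the straddling windows", {
  L <- 1000
  labels <- c(rep("walk", 487), rep("run", L - 487))
  s <- imu_series(matrix(rnorm(L * 3), L, 3), labels, fs = 20)
  seg <- segment_windows(s, 200, 100)
  kept <- enforce_label_consistency(seg)
  # brute force: a window is kept iff its label slice is constant
  brute_keep <- sapply(seg$start, function(st) {
    length(unique(labels[(st + 1):(st + 200)])) == 1
  })
  expect_identical(nrow(kept), as.integer(sum(brute_keep)))
  expect_identical(kept$start, seg$start[brute_keep])
  expect_identical(unique(kept$label), c("walk", "run"))

  # uniform labels: everything is retained
  s2 <- imu_series(matrix(rnorm(600), 200, 3), rep("walk", 200), fs = 20)
  expect_identical(nrow(enforce_label_consistency(segment_windows(s2))), 1L)

  # per-record labels trivially pass
  s3 <- imu_series(matrix(rnorm(900), 300, 3), "golf", fs = 20)
  expect_identical(nrow(enforce_label_consistency(segment_windows(s3))), 2L)
})

test_that("normalization statistics are exact, train-only, and invertible in effect", {
  set.seed(5)
  w <- lapply(1:3, function(i) matrix(rnorm(20 * 2, mean = i, sd = i), 20, 2))
  st <- fit_normalizer(w)
  flat <- do.call(rbind, w)
  expect_equal(st$mean, colMeans(flat))
  expect_equal(st$sd, sqrt(colMeans(flat^2) - colMeans(flat)^2))

  normed <- apply_normalizer(st, w)
  nf <- do.call(rbind, normed)
  expect_lt(max(abs(colMeans(nf))), 1e-6)
  expect_lt(max(abs(apply(nf, 2, function(c) sqrt(mean(c^2) - mean(c)^2)) - 1)), 1e-6)

  # affine invariance: scaling and shifting an axis yields the same
  # normalized output
  w2 <- lapply(w, function(m) {
    m[, 1] <- m[, 1] * 10 + 5
    m
  })
  st2 <- fit_normalizer(w2)
  expect_equal(apply_normalizer(st2, w2), normed, tolerance = 1e-10)

  # mutation check: validation data never influences the training stats
  st_before <- fit_normalizer(w)
  val <- list(matrix(rnorm(40, 100, 50), 20, 2))
  st_after <- fit_normalizer(w)
  expect_identical(st_before, st_after)

  expect_warning(fit_normalizer(list(matrix(1, 5, 2), matrix(1, 5, 2))), "constant")
  expect_error(fit_normalizer(list(matrix(1, 5, 2))), "at least 2")
})

test_that("label encoding is lexicographic, bijective and strict about unseen labels", {
  enc <- encode_labels(c("walk", "run", "walk"))
  expect_identical(enc$map$class, c("run", "walk"))
  expect_identical(enc$ids, c(1L, 0L, 1L))
  expect_identical(decode_labels(enc$ids, enc$map), c("walk", "run", "walk"))

  six <- c("f", "a", "c", "e", "b", "d")
  enc6 <- encode_labels(six)
  expect_identical(sort(enc6$map$id), 0:5)
  # bijection by enumeration
  for (cl in six) {
    expect_identical(decode_labels(encode_labels(cl, enc6$map)$ids, enc6$map), cl)
  }
  expect_error(encode_labels("zebra", enc6$map), "unseen")
  expect_error(encode_labels(character(0)), "empty")
})

test_that("the pipeline is shape-conservative and respects the filtering order", {
  set.seed(6)
  L <- 300
  s <- imu_series(matrix(rnorm(L * 3), L, 3), rep("a", L), fs = 20)
  den <- denoise_series(s)
  expect_identical(dim(den$samples), dim(s$samples))
  # Butterworth first, then Savitzky-Golay
  manual <- savgol_smooth(lowpass_filter(s$samples, s$fs))
  expect_equal(den$samples, manual, tolerance = 1e-12)
  # the no-filter path leaves samples untouched
  expect_identical(denoise_series(s, filter = FALSE)$samples, s$samples)
})
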