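sine_signal <- function(freqs, amps, fs = 44100, dur = 1) {
  tt <- (seq_len(fs * dur) - 1) / fs
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * tt),
                      numeric(length(tt))))
  audio_signal(x / max(1, max(abs(x))) * 0.9, fs)
}

test_that("periodogram localizes a pure tone and returns n_freq values", {
  # 1 s at 44100 Hz with n_freq = 22051 puts the grid exactly on integer Hz
  sig <- sine_signal(1000, 1)
  ps <- compute_periodogram(sig, n_freq = 22051L)
  expect_length(ps$power_db, 22051L)
  expect_length(ps$frequencies, 22051L)
  expect_equal(ps$frequencies[which.max(ps$power_db)], 1000)
  expect_equal(ps$frequencies[1], 0)
  expect_equal(ps$frequencies[22051], 22050)
})

test_that("the default frequency vector has 100000 values up to Nyquist", {
  sig <- synthesize_doppler_audio(tiny_config(seed = 31))
  ps <- compute_periodogram(sig)
  expect_length(ps$frequencies, 100000L)
  expect_equal(ps$frequencies[100000], 44100 / 2)
  expect_true(all(diff(ps$frequencies) > 0))
})

test_that("two tones with 10x amplitude ratio differ by 20 dB", {
  sig <- sine_signal(c(1000, 5000), c(0.5, 0.05))
  ps <- compute_periodogram(sig, n_freq = 22051L)
  p1 <- ps$power_db[ps$frequencies == 1000]
  p2 <- ps$power_db[ps$frequencies == 5000]
  expect_equal(p1 - p2, 20, tolerance = 0.5)
})

test_that("all-zero signal floors at -300 dB with a warning", {
  sig <- audio_signal(numeric(44100) + 0, 44100)
  expect_warning(ps <- compute_periodogram(sig, n_freq = 1000L), "all-zero")
  expect_true(all(ps$power_db == -300))
})

test_that("binning averages dB in blocks of bin_size and drops the remainder", {
  ps <- structure(list(frequencies = as.numeric(1:200),
                       power_db = as.numeric(1:200)),
                  class = "power_spectrum")
  b <- bin_spectrum(ps, bin_size = 80L)
  expect_length(b$bin_power_db, 2L)  # remainder of 40 dropped
  expect_equal(b$bin_power_db, c(40.5, 120.5))
  expect_equal(b$bin_centers, c(40.5, 120.5))
  const <- structure(list(frequencies = as.numeric(1:160),
                          power_db = rep(7, 160)),
                     class = "power_spectrum")
  expect_equal(bin_spectrum(const, 80L)$bin_power_db, c(7, 7))
})

test_that("100000 points binned by 80 give 1250 bins; band 10-200 gives 191", {
  ps <- structure(list(frequencies = as.numeric(1:100000),
                       power_db = rnorm(100000)),
                  class = "power_spectrum")
  b <- bin_spectrum(ps, 80L)
  expect_identical(length(b$bin_power_db), 1250L)
  band <- select_band(b, 10L, 200L)
  expect_identical(length(band$bin_power_db), 191L)
  expect_identical(band$band, c(10L, 200L))
  expect_equal(band$bin_centers[1], b$bin_centers[10])
  # identity and single-bin edge cases
  expect_equal(select_band(b, 1L, 1250L)$bin_power_db, b$bin_power_db)
  expect_length(select_band(b, 42L, 42L)$bin_power_db, 1L)
  expect_error(select_band(b, 100L, 2000L), class = "validation_error")
})

test_that("prominences and widths match the worked example", {
  y <- c(0, 1, 0, 3, 0, 2, 0)
  pk <- find_prominent_peaks(make_binned(y), n_peaks = 3L)
  expect_equal(pk$bin_index, c(2, 4, 6))
  expect_equal(pk$prominence, c(1, 3, 2))
  expect_equal(pk$height, c(1, 3, 2))
  # central peak: reference level 1.5, crossings interpolate to width 1.0
  expect_equal(pk$width[2], 1.0)
})

test_that("monotone spectra yield no peaks and an error", {
  expect_error(find_prominent_peaks(make_binned(1:20), n_peaks = 1L),
               class = "insufficient_peaks")
  expect_error(find_prominent_peaks(make_binned(c(0, 1, 0, 2, 0)), n_peaks = 5L),
               class = "insufficient_peaks")
})

test_that("peak detection matches the brute-force oracle on random spectra", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(10:50, 1)
    y <- rnorm(n)
    if (rep %% 3 == 0) y <- round(y * 2) / 2  # force ties and plateaus
    oracle <- oracle_peaks(y)
    if (is.null(oracle) || nrow(oracle) == 0) {
      expect_error(find_prominent_peaks(make_binned(y), n_peaks = 1L),
                   class = "insufficient_peaks")
      next
    }
    got <- find_prominent_peaks(make_binned(y), n_peaks = nrow(oracle))
    got <- got[order(got$bin_index), ]
    expect_equal(got$bin_index, oracle$bin_index)
    expect_equal(got$prominence, oracle$prominence, tolerance = 1e-12)
    expect_equal(got$width, oracle$width, tolerance = 1e-12)
  }
})

test_that("peak feature matrices are ordered and validated", {
  set.seed(7)
  peaks <- data.frame(prominence = runif(10), height = runif(10),
                      width = runif(10), location = sample(10))
  m <- extract_peak_features(peaks, "r1")
  expect_s3_class(m, "peak_feature_matrix")
  expect_identical(dim(m$features), c(10L, 4L))  # 40 values
  expect_true(!is.unsorted(m$features$location))
  expect_error(extract_peak_features(peaks[1:9, ], "r1"),
               class = "validation_error")
  # duplicate locations break ties by descending prominence
  dup <- data.frame(prominence = c(1, 5, 3), height = 1, width = 1,
                    location = c(100, 50, 50))
  md <- extract_peak_features(dup, "r2", n_peaks = 3L)
  expect_equal(md$features$prominence, c(5, 3, 1))
})

test_that("fingerprint reduction follows the three normalization stages", {
  # two recordings built from simple numbers so every stage is hand-checkable
  a <- fake_pfm("a", prominence = rep(2, 10), height = rep(1, 10),
                width = rep(4, 10), location = seq(100, 1000, by = 100))
  b <- fake_pfm("b", prominence = rep(4, 10), height = rep(2, 10),
                width = rep(8, 10), location = rep(500, 10))
  coll <- build_fingerprints(list(a, b))
  fp <- coll$fingerprints
  # stage 1 maxima pool over both recordings
  expect_equal(unname(coll$stage1_max),
               c(4, 2, 8, 1000), tolerance = 1e-12)
  # recording a: prominences 2/4 = 0.5 each, sum 5; b: sum 10 -> stage 3
  expect_equal(unname(fp[, "sum_prominence"]), c(0.5, 1))
  expect_equal(unname(fp[, "sum_height"]), c(0.5, 1))
  expect_equal(unname(fp[, "sum_width"]), c(0.5, 1))
  # b's locations are constant -> var 0; column max over recordings = 1
  expect_equal(unname(fp["b", "var_location"]), 0)
  expect_equal(unname(apply(fp, 2, max)), rep(1, 5))
})

test_that("stage-1 normalization of (2, 4, 8) scales to (0.25, 0.5, 1)", {
  vals <- c(2, 4, 8)
  expect_equal(vals / max(vals), c(0.25, 0.5, 1))
  # the same scaling inside build_fingerprints, via a recording whose 10
  # normalized prominences are each 0.1 -> pre-stage-3 sum of 1.0
  a <- fake_pfm("a", prominence = rep(1, 10), height = rep(1, 10),
                width = rep(1, 10), location = 1:10)
  b <- fake_pfm("b", prominence = rep(10, 10), height = rep(1, 10),
                width = rep(1, 10), location = 1:10)
  coll <- build_fingerprints(list(a, b))
  # a's normalized prominences are 0.1 each; sums 1 and 10; after stage 3:
  expect_equal(unname(coll$fingerprints[, "sum_prominence"]), c(0.1, 1))
})

test_that("degenerate pooled maxima are rejected", {
  z <- fake_pfm("z", prominence = rep(0, 10), height = rep(0, 10),
                width = rep(0, 10), location = 1:10)
  z2 <- fake_pfm("z2", prominence = rep(0, 10), height = rep(0, 10),
                 width = rep(0, 10), location = 1:10)
  expect_error(build_fingerprints(list(z, z2)), class = "degenerate_feature")
  expect_error(build_fingerprints(list(z)), class = "validation_error")
})

test_that("apply_fingerprint reproduces indexed rows and is linear", {
  set.seed(42)
  mats <- lapply(1:4, function(i)
    fake_pfm(paste0("r", i), prominence = runif(10, 1, 5),
             height = runif(10, 40, 80), width = runif(10, 1, 10),
             location = sort(runif(10, 100, 4000))))
  coll <- build_fingerprints(mats)
  # idempotence: projecting an indexed recording returns its row
  fp1 <- apply_fingerprint(mats[[1]], coll)
  expect_equal(unname(fp1), unname(coll$fingerprints[1, ]), tolerance = 1e-12)
  # doubling prominences doubles sum_prominence under frozen constants
  doubled <- mats[[1]]
  doubled$features$prominence <- 2 * doubled$features$prominence
  fp2 <- apply_fingerprint(doubled, coll)
  expect_equal(fp2[["sum_prominence"]], 2 * fp1[["sum_prominence"]])
  expect_equal(fp2[["mean_location"]], fp1[["mean_location"]])
  # all-zero matrix projects to all zeros (variance of constants is 0)
  zero <- fake_pfm("z", prominence = rep(0, 10), height = rep(0, 10),
                   width = rep(0, 10), location = rep(0, 10))
  expect_equal(unname(apply_fingerprint(zero, coll)), rep(0, 5))
  # missing constants
  broken <- coll; broken$stage1_max <- NULL
  expect_error(apply_fingerprint(mats[[1]], broken), class = "state_error")
})

test_that("fingerprinting is deterministic and gain shifts only sum_height", {
  sig <- synthesize_doppler_audio(tiny_config(seed = 77))
  m1 <- fingerprint_audio(sig, n_freq = 20000L)
  m2 <- fingerprint_audio(sig, n_freq = 20000L)
  expect_identical(m1$features, m2$features)
  # scaling the audio by g shifts all dB values by 20 log10(g): prominences,
  # widths and locations are unchanged, heights shift
  quiet <- sig
  quiet$samples <- sig$samples * 0.1
  m3 <- fingerprint_audio(quiet, n_freq = 20000L)
  expect_equal(m3$features$prominence, m1$features$prominence, tolerance = 1e-9)
  expect_equal(m3$features$width, m1$features$width, tolerance = 1e-9)
  expect_equal(m3$features$location, m1$features$location)
  expect_equal(m3$features$height, m1$features$height - 20, tolerance = 1e-9)
})
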