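test_that("preprocessing z-scores every channel per trial", {
  rec <- toy_recording(duration_s = 20)
  out <- preprocess_recording(rec, 0.5, 70)
  mu <- rowMeans(out$data)
  sdv <- apply(out$data, 1, sd) * sqrt((n_samples(out) - 1) / n_samples(out))
  expect_true(all(abs(mu) < 1e-8))
  expect_true(all(abs(sdv - 1) < 1e-6))
  expect_equal(out$fs, 70)
  expect_identical(out$label, rec$label)
})

test_that("zero-variance channels come back as zeros with a warning", {
  rec <- toy_recording(duration_s = 10)
  rec$data[3, ] <- 42
  expect_warning(out <- preprocess_recording(rec, 0, rec$fs), "zero-variance")
  expect_true(all(out$data[3, ] == 0))
  expect_true(all(abs(rowMeans(out$data[-3, ])) < 1e-8))
})

test_that("upsampling is refused and bad cutoffs are rejected", {
  rec <- toy_recording(duration_s = 5, fs = 70)
  expect_error(preprocess_recording(rec, 0.5, 128), "upsampling")
  expect_error(preprocess_recording(rec, 40, 70), "below target_fs / 2",
               fixed = TRUE)
})

test_that("the high-pass filter removes DC and passes the alpha band", {
  fs <- 70; tt <- (0:(fs * 30 - 1)) / fs
  x <- 5 + sin(2 * pi * 10 * tt)
  rec <- eeg_recording(rbind(x, x), fs, c("a", "b"))
  out <- preprocess_recording(rec, 0.5, fs, zscore = FALSE)
  # DC gone, 10 Hz amplitude essentially untouched
  expect_lt(abs(mean(out$data[1, ])), 1e-2)
  p <- band_power(out, frequency_band(9, 11))
  expect_equal(unname(p[1]), 0.5, tolerance = 0.01)
})

test_that("downsampling anti-aliases: content above the new Nyquist drops >= 20 dB", {
  fs <- 8192; tt <- (0:(fs * 2 - 1)) / fs
  x <- sin(2 * pi * 40 * tt)                 # above the 35 Hz output Nyquist
  rec <- eeg_recording(rbind(x, x), fs, c("a", "b"))
  out <- preprocess_recording(rec, 0, 70, zscore = FALSE)
  expect_equal(out$fs, 70)
  # direct FFT oracle on the resampled signal: total power in the aliased
  # region (25-35 Hz; 40 Hz folds to 30 Hz) must be >= 20 dB below the
  # original passband power A^2/2 = 0.5
  alias_p <- unname(band_power(out, frequency_band(25, 34.9))[1])
  expect_lt(alias_p, 0.5 / 100)
  # and a passband tone survives the same path
  x2 <- sin(2 * pi * 10 * tt)
  rec2 <- eeg_recording(rbind(x2, x2), fs, c("a", "b"))
  out2 <- preprocess_recording(rec2, 0, 70, zscore = FALSE)
  expect_equal(unname(band_power(out2, frequency_band(9, 11))[1]), 0.5,
               tolerance = 0.02)
})

test_that("recordings reject non-finite data and mismatched names", {
  expect_error(eeg_recording(matrix(c(1, NA, 3, 4), 2), 70, c("a", "b")),
               "non-finite")
  expect_error(eeg_recording(matrix(1:6, 2), 70, c("a", "b", "c")),
               "does not match")
  expect_error(eeg_recording(matrix(1:4, 2), 70, c("a", "a")), "unique")
})
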