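test_that("band powers obey Parseval's identity on a disjoint band cover", {
  set.seed(21)
  for (N in c(140, 141, 700)) {
    x <- matrix(rnorm(3 * N), 3)
    x <- x - rowMeans(x)                          # DC-free
    rec <- eeg_recording(x, 70, c("a", "b", "c"))
    res <- 70 / N
    cuts <- c(4, 13, 22, 31) * res               # edges between bin centers
    bands <- list(frequency_band(1e-9, cuts[1] + res / 2),
                  frequency_band(cuts[1] + res / 2 + 1e-9, cuts[2] + res / 2),
                  frequency_band(cuts[2] + res / 2 + 1e-9, cuts[3] + res / 2),
                  frequency_band(cuts[3] + res / 2 + 1e-9, 35))
    tot <- Reduce(`+`, lapply(bands, function(b) band_power(rec, b)))
    expect_equal(unname(tot), unname(rowMeans(x^2)), tolerance = 1e-9)
  }
})

test_that("a pure in-band sinusoid carries its full power in that band", {
  fs <- 70; tt <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * 10 * tt)                      # exactly 100 cycles
  rec <- eeg_recording(rbind(x, 2 * x), fs, c("a", "b"))
  p <- band_power(rec, frequency_band(8, 13))
  expect_equal(unname(p), c(0.5, 2.0), tolerance = 0.01)
  out <- band_power(rec, frequency_band(20, 30))
  expect_true(all(out < 1e-6))
})

test_that("degenerate inputs are handled", {
  rec <- eeg_recording(matrix(0, 2, 70), 70, c("a", "b"))
  expect_identical(unname(band_power(rec, frequency_band(8, 13))), c(0, 0))
  tiny <- eeg_recording(matrix(rnorm(16), 2), 70, c("a", "b"))
  expect_error(band_power(tiny, frequency_band(8, 8.6)), "no FFT bins")
  expect_error(band_power(rec, frequency_band(30, 40)), "Nyquist")
})
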