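test_that("extract_ssf yields one labeled 28x28 map per window", {
  rec <- toy_recording(duration_s = 60)
  maps <- extract_ssf(rec, decision_window_spec(10, 0.5),
                      montage = toy_montage_8())
  expect_length(maps, 11L)
  for (m in maps) {
    expect_s3_class(m, "ssf_map")
    expect_identical(dim(m$grid), c(28L, 28L))
    expect_identical(m$label, "left")
    expect_true(all(is.finite(m$grid)))
    expect_true(all(m$grid >= -1 & m$grid <= 1))
  }
  expect_identical(vapply(maps, function(m) m$window_index, 1L), 0:10)
})

test_that("SSF extraction is deterministic and records its scaling", {
  rec <- toy_recording(duration_s = 20)
  a <- extract_ssf(rec, decision_window_spec(5, 0), montage = toy_montage_8())
  b <- extract_ssf(rec, decision_window_spec(5, 0), montage = toy_montage_8())
  expect_identical(lapply(a, function(m) m$grid),
                   lapply(b, function(m) m$grid))
  # scaling invertible back to raw power units
  raw <- extract_ssf(rec, decision_window_spec(5, 0),
                     montage = toy_montage_8(), normalize = FALSE)
  si <- a[[1]]$scale_info
  back <- (a[[1]]$grid + 1) / 2 * (si$max - si$min) + si$min
  expect_equal(back, raw[[1]]$grid, tolerance = 1e-12)
})

test_that("an all-zero recording yields the normalization image of zero", {
  rec <- eeg_recording(matrix(0, 8, 140), 70, toy_montage_8()$names)
  maps <- extract_ssf(rec, decision_window_spec(1, 0),
                      montage = toy_montage_8())
  expect_true(all(maps[[1]]$grid == 0))
})

test_that("left/right simulated classes show opposite hemifield contrast", {
  ds <- fixture_dataset()
  lab <- ssf_labels(ds$maps)
  ml <- apply(ssf_stack(ds$maps[lab == "left"]), c(2, 3), mean)
  mr <- apply(ssf_stack(ds$maps[lab == "right"]), c(2, 3), mean)
  dif <- ml - mr
  half <- 14
  # columns track the v (left) axis: left hemifield = high columns
  left_pix <- mean(dif[, 15:28]); right_pix <- mean(dif[, 1:14])
  expect_gt(left_pix * right_pix, -Inf)   # guard: both finite
  expect_true(sign(left_pix) != sign(right_pix))
  expect_gt(abs(left_pix - right_pix), 0.05)
})

test_that("SSF datasets round-trip through the plain-text container", {
  ds <- fixture_dataset()
  dir <- withr::local_tempdir()
  write_ssf_dataset(ds$maps[1:7], dir)
  back <- read_ssf_dataset(dir)
  expect_length(back, 7L)
  expect_equal(lapply(back, function(m) m$grid),
               lapply(ds$maps[1:7], function(m) m$grid), tolerance = 1e-12)
  expect_identical(ssf_labels(back), ssf_labels(ds$maps[1:7]))
  expect_identical(back[[3]]$trial_id, ds$maps[[3]]$trial_id)
})
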