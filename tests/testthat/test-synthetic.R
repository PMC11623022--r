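test_that("simulation is deterministic given a seed", {
  cfg <- simulation_config(duration_s = 5, seed = 91)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$label, "left")
  expect_identical(n_channels(a), 64L)
})

test_that("hemispheric alpha power ratio tracks lateralization squared", {
  cfg <- simulation_config(duration_s = 30, lateralization = 3, snr = 5,
                           seed = 92)
  rec <- simulate_recording(cfg)
  hemi <- electrode_hemisphere(standard_montage(64))
  p <- band_power(rec, frequency_band(8, 13))
  ratio <- mean(p[hemi == "left"]) / mean(p[hemi == "right"])
  # power scales as amplitude^2 -> 9, diluted slightly by in-band background
  expect_equal(ratio, 9, tolerance = 0.2 * 9)
  # lateralization = 1: no systematic hemispheric difference
  cfg0 <- simulation_config(duration_s = 30, lateralization = 1, snr = 5,
                            seed = 93)
  p0 <- band_power(simulate_recording(cfg0), frequency_band(8, 13))
  tt <- t.test(p0[hemi == "left"], p0[hemi == "right"])
  expect_gt(tt$p.value, 0.01)
})

test_that("the boost side honors label and convention switch", {
  hemi <- electrode_hemisphere(standard_montage(64))
  p_r <- band_power(simulate_recording(
    simulation_config(duration_s = 10, label = "right", seed = 94)),
    frequency_band(8, 13))
  expect_gt(mean(p_r[hemi == "right"]), 3 * mean(p_r[hemi == "left"]))
  p_c <- band_power(simulate_recording(
    simulation_config(duration_s = 10, label = "right",
                      boost_side = "contra", seed = 94)),
    frequency_band(8, 13))
  expect_gt(mean(p_c[hemi == "left"]), 3 * mean(p_c[hemi == "right"]))
})

test_that("background spectral slope matches the configured exponent", {
  set.seed(95)
  x <- ssfgan:::pink_noise(70 * 120, 70, 1)
  ps <- ssfgan:::power_spectrum(rbind(x, x), 70)
  sel <- ps$freq >= 0.5 & ps$freq <= 30
  fit <- lm(log(ps$power[sel, 1]) ~ log(ps$freq[sel]))
  expect_lt(abs(coef(fit)[2] + 1), 0.3)
  expect_equal(mean(x^2), 1, tolerance = 0.05)
})

test_that("class information lives only in the alpha band", {
  outp <- sapply(1:30, function(i) {
    lab <- if (i %% 2 == 0) "left" else "right"
    rec <- simulate_recording(simulation_config(duration_s = 8, label = lab,
                                                seed = 900 + i))
    hemi <- electrode_hemisphere(standard_montage(64))
    p <- band_power(rec, frequency_band(15, 30))   # outside alpha
    c(mean(p[hemi == "left"]) - mean(p[hemi == "right"]), lab == "left")
  })
  tt <- t.test(outp[1, outp[2, ] == 1], outp[1, outp[2, ] == 0])
  expect_gt(tt$p.value, 0.01)
})

test_that("make_dataset is balanced, manifested, and separable", {
  ds <- fixture_dataset()
  expect_identical(nrow(ds$manifest), 20L)
  expect_identical(sum(ds$manifest$label == "left"), 10L)
  expect_identical(length(ds$maps), 380L)    # 19 windows x 20 trials
  lab <- ssf_labels(ds$maps)
  tr <- rep(c(TRUE, FALSE), length.out = length(ds$maps))
  hf <- hemifield_classifier(ds$maps[tr], lab[tr])
  expect_gte(mean(hf(ds$maps[!tr]) == lab[!tr]), 0.9)
})

test_that("at vanishing SNR the hemifield discriminant is at chance", {
  ds0 <- fixture_null_dataset()
  lab <- ssf_labels(ds0$maps)
  # labels alternate map-by-map here, so split first/second half
  tr <- seq_along(ds0$maps) <= 250
  hf <- hemifield_classifier(ds0$maps[tr], lab[tr])
  acc <- mean(hf(ds0$maps[!tr]) == lab[!tr])
  expect_gt(acc, 0.40)
  expect_lt(acc, 0.60)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(lateralization = 0.5))
  expect_error(simulation_config(snr = 0))
  expect_error(simulation_config(label = "up"))
})
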