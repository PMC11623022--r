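#' Synthetic EEG simulation configuration
#'
#' Describes one simulated trial: 1/f^beta background noise in every channel
#' plus an alpha-band sinusoid whose amplitude is larger by the factor
#' `lateralization` over one hemisphere, keyed to the attention label. `snr`
#' is the alpha-to-background power ratio on the unboosted hemisphere (the
#' background has unit power per channel). The boosted side for a `"left"`
#' label is set by `boost_side`: `"ipsi"` boosts the left hemisphere
#' (electrode y > 0), `"contra"` the right. The physiological direction of
#' alpha lateralization is debated; recovery experiments only require the
#' mapping to be consistent, and it is configurable.
#'
#' @param n_channels 64 (default) or 32, matching [standard_montage()].
#' @param fs sampling rate in Hz (default 70, the post-resampling rate).
#' @param duration_s trial duration in seconds.
#' @param label `"left"` or `"right"`.
#' @param alpha_freq_hz alpha oscillation frequency in `[8, 13]`.
#' @param lateralization hemispheric alpha amplitude ratio (>= 1).
#' @param snr alpha-to-background power ratio (> 0) on the unboosted side.
#' @param background_exponent 1/f spectral slope beta of the background.
#' @param boost_side `"ipsi"` or `"contra"` (see above).
#' @param seed RNG seed for reproducible trials.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_channels = 64L, fs = 70, duration_s = 30,
                              label = "left", alpha_freq_hz = 10,
                              lateralization = 3, snr = 5,
                              background_exponent = 1, boost_side = "ipsi",
                              seed = NULL) {
  stopifnot(lateralization >= 1, snr > 0, duration_s > 0,
            alpha_freq_hz >= 8, alpha_freq_hz <= 13)
  label <- match.arg(label, c("left", "right"))
  boost_side <- match.arg(boost_side, c("ipsi", "contra"))
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, label = label,
                 alpha_freq_hz = alpha_freq_hz,
                 lateralization = lateralization, snr = snr,
                 background_exponent = background_exponent,
                 boost_side = boost_side, seed = seed),
            class = "simulation_config")
}

# 1/f^beta noise of length n, unit variance, via inverse FFT of shaped
# amplitudes with random phases.
pink_noise <- function(n, fs, beta) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  amp <- f^(-beta / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Mod(spec[nf]))   # real Nyquist bin
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Simulate one multichannel EEG trial
#'
#' Each channel is unit-power 1/f^beta background noise plus an alpha
#' sinusoid with channel-specific random phase. On the hemisphere keyed to
#' the label (see [simulation_config()]) the alpha amplitude is multiplied
#' by `lateralization`; midline channels carry the base amplitude. Channel
#' to hemisphere assignment comes from the sign of the montage y coordinate.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @param montage optional [electrode_montage()]; defaults to
#'   [standard_montage()] at `cfg$n_channels`.
#' @param subject_id,trial_id provenance identifiers.
#' @return An [eeg_recording()] labeled per the config.
#' @export
simulate_recording <- function(cfg, montage = NULL,
                               subject_id = "sim", trial_id = "t1") {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(montage)) montage <- standard_montage(cfg$n_channels)
  if (length(montage$names) != cfg$n_channels)
    stop("montage channel count (", length(montage$names),
         ") does not match cfg$n_channels (", cfg$n_channels, ")")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  hemi <- electrode_hemisphere(montage)
  boosted_hemi <- if (cfg$boost_side == "ipsi") cfg$label
                  else setdiff(c("left", "right"), cfg$label)
  amp_base <- sqrt(2 * cfg$snr)      # sinusoid power A^2/2 = snr * bg power 1
  tt <- (seq_len(n) - 1) / cfg$fs
  x <- matrix(0, cfg$n_channels, n)
  for (i in seq_len(cfg$n_channels)) {
    a <- amp_base * if (hemi[i] == boosted_hemi) cfg$lateralization else 1
    x[i, ] <- pink_noise(n, cfg$fs, cfg$background_exponent) +
      a * sin(2 * pi * cfg$alpha_freq_hz * tt + stats::runif(1, 0, 2 * pi))
  }
  eeg_recording(x, cfg$fs, montage$names, subject_id = subject_id,
                trial_id = trial_id, label = cfg$label)
}

#' Build a balanced labeled SSF dataset from simulated trials
#'
#' Simulates `n_per_class` trials per class from the template config
#' (alternating labels, fresh sub-seed per trial), extracts SSF maps from
#' each with [extract_ssf()], and records every per-trial configuration in a
#' manifest for recovery experiments.
#'
#' @param n_per_class simulated trials per class.
#' @param cfg_template a [simulation_config()]; its label is overridden.
#' @param window_spec a [decision_window_spec()].
#' @param band a [frequency_band()].
#' @param seed master seed; trial `i` uses `seed + i`.
#' @param montage optional montage (defaults to the standard one).
#' @param subject_id subject identifier stamped on all trials.
#' @return List with `maps` (list of [ssf_map()]) and `manifest`
#'   (`data.frame`, one row per trial: label, seed, lateralization, snr).
#' @export
make_dataset <- function(n_per_class, cfg_template = simulation_config(),
                         window_spec = decision_window_spec(2, 0.5),
                         band = frequency_band(), seed = 1L,
                         montage = NULL, subject_id = "sim") {
  if (is.null(montage)) montage <- standard_montage(cfg_template$n_channels)
  montage <- project_montage(montage)
  labels <- rep(c("left", "right"), n_per_class)
  maps <- list(); manifest <- NULL
  for (i in seq_along(labels)) {
    cfg <- cfg_template
    cfg$label <- labels[i]
    cfg$seed <- seed + i
    rec <- simulate_recording(cfg, montage, subject_id = subject_id,
                              trial_id = sprintf("trial%03d", i))
    maps <- c(maps, extract_ssf(rec, window_spec, band, montage))
    manifest <- rbind(manifest,
                      data.frame(trial_id = sprintf("trial%03d", i),
                                 label = labels[i], seed = cfg$seed,
                                 lateralization = cfg$lateralization,
                                 snr = cfg$snr, fs = cfg$fs,
                                 duration_s = cfg$duration_s,
                                 subject_id = subject_id))
  }
  list(maps = maps, manifest = manifest)
}
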