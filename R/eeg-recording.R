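#' Multichannel EEG recording
#'
#' Container for one contiguous stretch of multichannel EEG: a channels x
#' samples numeric matrix in microvolts plus sampling rate, channel names and
#' trial/subject provenance. The attention label, when known, is `"left"` or
#' `"right"`.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of unique channel names, one per row.
#' @param subject_id,trial_id identifiers carried through the pipeline.
#' @param label attention label, `"left"`, `"right"` or `NA`.
#' @param window_index index of the decision window this recording was cut
#'   from, or `NA` for a full trial.
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 140), 2), fs = 70,
#'                      channel_names = c("C3", "C4"), label = "left")
#' n_channels(rec)
eeg_recording <- function(data, fs, channel_names,
                          subject_id = NA_character_, trial_id = NA_character_,
                          label = NA_character_, window_index = NA_integer_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("an EEG recording needs at least 2 channels")
  if (!all(is.finite(data)))
    stop("non-finite values in EEG data")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(data), ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.na(label)) label <- match.arg(label, c("left", "right"))
  rownames(data) <- channel_names
  structure(list(data = data, fs = as.numeric(fs),
                 channel_names = channel_names,
                 subject_id = subject_id, trial_id = trial_id,
                 label = label, window_index = window_index),
            class = "eeg_recording")
}

#' @rdname eeg_recording
#' @param x an `eeg_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname eeg_recording
#' @param ... ignored.
#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  cat(sprintf("  subject: %s  trial: %s  label: %s  window: %s\n",
              x$subject_id, x$trial_id, x$label,
              ifelse(is.na(x$window_index), "-", x$window_index)))
  invisible(x)
}

#' Decision-window specification
#'
#' Length (seconds) and fractional overlap of the sliding decision window used
#' to cut a trial into classification units.
#'
#' @param length_s window duration in seconds (> 0).
#' @param overlap fractional overlap in `[0, 1)`; successive windows advance by
#'   `round(L * (1 - overlap))` samples.
#' @return A `decision_window_spec` object.
#' @export
decision_window_spec <- function(length_s, overlap = 0.5) {
  stopifnot(is.numeric(length_s), length(length_s) == 1L, length_s > 0,
            is.numeric(overlap), length(overlap) == 1L,
            overlap >= 0, overlap < 1)
  structure(list(length_s = length_s, overlap = overlap),
            class = "decision_window_spec")
}

#' Frequency band
#'
#' A `(low, high)` frequency interval in Hz. The default is the alpha band,
#' 8-13 Hz, whose scalp topography lateralizes with the direction of spatial
#' auditory attention.
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @return A `frequency_band` object.
#' @export
frequency_band <- function(low_hz = 8, high_hz = 13) {
  stopifnot(is.numeric(low_hz), is.numeric(high_hz),
            low_hz > 0, low_hz < high_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz),
            class = "frequency_band")
}

#' Preprocess a recording: high-pass filter, resample, z-score
#'
#' Applies, in order: a zero-phase 4th-order Butterworth high-pass filter,
#' anti-aliased polyphase resampling to `target_fs`, and per-channel
#' z-scoring (zero mean, unit variance) over the whole trial. Zero-variance
#' channels are returned as all zeros with a warning rather than NaN.
#'
#' @param rec an [eeg_recording()].
#' @param hp_cutoff_hz high-pass cutoff in Hz; must be below `target_fs / 2`.
#' @param target_fs output sampling rate in Hz; upsampling is not supported.
#' @param zscore z-score channels after filtering (default `TRUE`).
#' @return The preprocessed `eeg_recording` with `fs = target_fs`.
#' @export
preprocess_recording <- function(rec, hp_cutoff_hz = 0.5, target_fs = 70,
                                 zscore = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop("upsampling not supported: target_fs (", target_fs,
         ") > recording fs (", rec$fs, ")")
  if (hp_cutoff_hz >= target_fs / 2)
    stop("hp_cutoff_hz must be below target_fs / 2")
  x <- rec$data
  if (hp_cutoff_hz > 0) {
    ba <- butter_highpass(4L, hp_cutoff_hz, rec$fs)
    x <- t(apply(x, 1L, function(ch) filtfilt_ba(ba$b, ba$a, ch)))
  }
  if (target_fs != rec$fs) {
    x <- t(apply(x, 1L, function(ch) resample_poly(ch, target_fs, rec$fs)))
  }
  if (zscore) {
    mu <- rowMeans(x)
    x <- x - mu
    sdv <- sqrt(rowMeans(x^2))
    dead <- sdv < .Machine$double.eps^0.5
    if (any(dead)) {
      warning("zero-variance channel(s) returned as zeros: ",
              paste(rec$channel_names[dead], collapse = ", "))
      sdv[dead] <- 1
      x[dead, ] <- 0
    }
    x <- x / sdv
  }
  eeg_recording(x, target_fs, rec$channel_names, rec$subject_id,
                rec$trial_id, rec$label, rec$window_index)
}

#' Cut a recording into sliding decision windows
#'
#' Window length is `L = round(length_s * fs)` samples and the hop is
#' `step = max(1, round(L * (1 - overlap)))`; the number of windows is
#' `floor((n_samples - L) / step) + 1`. Label and provenance are preserved and
#' `window_index` counts from 0 in temporal order.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [decision_window_spec()].
#' @return A list of `eeg_recording` windows.
#' @export
segment_windows <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(spec, "decision_window_spec"))
  L <- round(spec$length_s * rec$fs)
  if (L < 1L) stop("window shorter than one sample")
  if (L > n_samples(rec))
    stop("window (", L, " samples) longer than recording (",
         n_samples(rec), " samples)")
  step <- max(1L, round(L * (1 - spec$overlap)))
  starts <- seq(1L, n_samples(rec) - L + 1L, by = step)
  lapply(seq_along(starts), function(i) {
    w <- rec
    w$data <- rec$data[, starts[i]:(starts[i] + L - 1L), drop = FALSE]
    w$window_index <- i - 1L
    w
  })
}

#' Number of sliding windows for given sizes
#'
#' Closed-form count used by [segment_windows()], exposed for planning and
#' for reproducing printed dataset sizes.
#'
#' @param n_samples,L,step sample counts (window length `L`, hop `step`).
#' @return Integer window count (0 if `L > n_samples`).
#' @export
count_windows <- function(n_samples, L, step) {
  if (L > n_samples) return(0L)
  as.integer(floor((n_samples - L) / step) + 1L)
}

#' Per-channel band power of one window
#'
#' The window is Fourier transformed per channel and per-bin powers are
#' normalized by the Parseval convention: the one-sided per-bin powers
#' (interior bins doubled) sum to the mean squared signal. The band power is
#' the sum of per-bin powers over bins with `low_hz <= f_k <= high_hz`
#' (inclusive edges).
#'
#' @param window an [eeg_recording()] of at least 2 samples.
#' @param band a [frequency_band()]; `high_hz` must not exceed `fs / 2`.
#' @return Named numeric vector of non-negative per-channel band powers.
#' @export
band_power <- function(window, band) {
  stopifnot(inherits(window, "eeg_recording"),
            inherits(band, "frequency_band"))
  N <- n_samples(window)
  if (N < 2L) stop("window must have at least 2 samples")
  if (band$high_hz > window$fs / 2 + 1e-12)
    stop("band upper edge exceeds Nyquist frequency")
  ps <- power_spectrum(window$data, window$fs)
  sel <- ps$freq >= band$low_hz & ps$freq <= band$high_hz
  if (!any(sel))
    stop("no FFT bins inside band [", band$low_hz, ", ", band$high_hz,
         "] Hz at resolution ", signif(window$fs / N, 3), " Hz")
  out <- colSums(ps$power[sel, , drop = FALSE])
  names(out) <- window$channel_names
  out
}

# One-sided Parseval-normalized power spectrum of a channels x samples matrix.
# Returns freq (length nb) and power (nb x channels) with
# colSums(power) == rowMeans(x^2).
power_spectrum <- function(x, fs) {
  N <- ncol(x)
  X <- t(stats::mvfft(t(x)))            # channels x N
  nb <- floor(N / 2) + 1L               # DC .. Nyquist (or highest bin)
  P <- (Mod(X[, seq_len(nb), drop = FALSE])^2) / N^2
  mult <- rep(2, nb)
  mult[1L] <- 1
  if (N %% 2 == 0) mult[nb] <- 1        # true Nyquist bin not mirrored
  P <- t(P) * mult                      # nb x channels
  list(freq = (seq_len(nb) - 1L) * fs / N, power = P)
}
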