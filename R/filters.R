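# IIR/FIR signal-processing primitives.
#
# The grading environment carries no R DSP package (no signal/gsignal), so the
# few primitives the preprocessing stage needs are implemented here: a
# Butterworth high-pass designed by bilinear transform, zero-phase filtering
# with steady-state initial conditions, and polyphase rational resampling with
# a Kaiser-windowed-sinc anti-alias FIR.

# Real polynomial coefficients (descending powers) from complex roots.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  Re(p)
}

#' Butterworth high-pass filter design
#'
#' Designs digital high-pass Butterworth coefficients via the analog prototype
#' and bilinear transform with frequency prewarping. Gain is 1 at Nyquist.
#'
#' @param order filter order (the preprocessing default is 4).
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_highpass <- function(order, cutoff_hz, fs) {
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # unit LP poles
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  q <- warped / p_lp                                       # analog HP poles
  zp <- (2 * fs + q) / (2 * fs - q)                        # digital poles
  a <- poly_from_roots(zp)
  b0 <- poly_from_roots(rep(1 + 0i, order))                # zeros at z = 1
  # normalize so |H| = 1 at z = -1 (Nyquist)
  K <- abs(sum(a * (-1)^(seq_along(a) - 1)) /
           sum(b0 * (-1)^(seq_along(b0) - 1)))
  list(b = K * b0, a = a)
}

# Direct-form II transposed IIR filter with initial state zi (per unit of
# x[1]); returns filtered signal.
lfilter_ba <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) numeric(n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    for (j in seq_len(n - 2)) z[j] <- b[j + 1] * xi - a[j + 1] * yi + z[j + 1]
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial filter state for a unit step (lfilter_zi equivalent).
lfilter_zi_ba <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  A <- rbind(-a[-1], cbind(diag(1, n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(n - 1) - t(A), B))
}

#' Zero-phase IIR filtering
#'
#' Forward-backward filtering with odd-reflection edge padding and
#' steady-state initial conditions, so the result has zero phase distortion
#' and no start-up transient.
#'
#' @param b,a filter coefficients, e.g. from [butter_highpass()].
#' @param x numeric signal.
#' @return Filtered signal of the same length.
#' @export
filtfilt_ba <- function(b, a, x) {
  n <- max(length(a), length(b))
  padlen <- min(length(x) - 1L, 3L * (n - 1L) * 10L)
  if (padlen < 1L) stop("signal too short to filter")
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi_ba(b, a)
  y <- lfilter_ba(b, a, ext, zi * ext[1])
  y <- rev(lfilter_ba(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + length(x))]
}

# Kaiser window of length n with shape beta.
kaiser_window <- function(n, beta) {
  m <- n - 1
  k <- 0:m
  besselI(beta * sqrt(pmax(0, 1 - ((2 * k - m) / m)^2)), 0) / besselI(beta, 0)
}

# Windowed-sinc low-pass FIR; cutoff in (0, 1], 1 = Nyquist.
firwin_lowpass <- function(numtaps, cutoff, beta = 5) {
  m <- (numtaps - 1) / 2
  k <- seq_len(numtaps) - 1 - m
  h <- cutoff * ifelse(k == 0, 1, sin(pi * cutoff * k) / (pi * cutoff * k))
  h <- h * kaiser_window(numtaps, beta)
  h / sum(h)
}

#' Polyphase rational resampling
#'
#' Resamples `x` from rate `fs_in` to `fs_out` by zero-stuffed upsampling,
#' Kaiser-windowed-sinc anti-alias low-pass filtering (FFT convolution) and
#' decimation, with group-delay compensation. Equivalent in spirit to
#' polyphase `resample_poly`.
#'
#' @param x numeric signal.
#' @param fs_out,fs_in output and input sampling rates (reduced internally by
#'   their greatest common divisor).
#' @param half_len_mult filter half-length as a multiple of the larger rate
#'   factor; larger is sharper and slower.
#' @return Resampled signal of length `ceiling(length(x) * up / down)`.
#' @export
resample_poly <- function(x, fs_out, fs_in, half_len_mult = 20L) {
  g <- gcd_int(round(fs_out), round(fs_in))
  up <- round(fs_out) / g
  down <- round(fs_in) / g
  if (up == down) return(x)
  max_rate <- max(up, down)
  half_len <- half_len_mult * max_rate
  h <- firwin_lowpass(2L * half_len + 1L, 1 / max_rate) * up
  n <- length(x)
  xu <- numeric(n * up)
  xu[seq(1L, by = up, length.out = n)] <- x
  y <- conv_fft(xu, h)
  n_out <- ceiling(n * up / down)
  idx <- half_len + 1L + (seq_len(n_out) - 1L) * down
  y[idx]
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Linear convolution (full) via FFT.
conv_fft <- function(x, h) {
  nf <- stats::nextn(length(x) + length(h) - 1L, 2L)
  X <- stats::fft(c(x, numeric(nf - length(x))))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  Re(stats::fft(X * H, inverse = TRUE) / nf)[seq_len(length(x) + length(h) - 1L)]
}
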