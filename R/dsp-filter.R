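#' Zero-phase Butterworth band-pass filter
#'
#' Filters forward and backward (so the effective order is twice `order` and
#' the group delay is zero) with a Butterworth band-pass designed by
#' [signal::butter()]. Before filtering, the trace is reflect-padded by
#' roughly three time constants of the slowest band edge and trimmed
#' afterwards, so edges carry no start-up transient.
#'
#' @param x a [trace()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order per pass (default 2; 4 effective).
#' @return a [trace()] of identical length.
#' @export
bandpass <- function(x, low, high, order = 2L) {
  stopifnot(inherits(x, "trace"))
  nyq <- x$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band edges must satisfy 0 < low < high < fs/2 = %g Hz", nyq),
         call. = FALSE)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  pad <- filter_pad_length(x$fs, low, length(x$samples))
  with_same_meta(x, filtfilt_padded(bf, x$samples, pad))
}

# ~3 time constants of the low band edge, capped at n - 1
filter_pad_length <- function(fs, low_edge, n) {
  as.integer(min(n - 1L, max(32L, ceiling(3 * fs / low_edge))))
}

# forward-backward filtering with odd (point-symmetric) reflection padding
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  left  <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n]  - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Remove power-line interference with a second-order IIR notch
#'
#' A biquad notch (zeros on the unit circle at the line frequency, poles
#' pulled inside by the chosen bandwidth) applied zero-phase at the line
#' frequency and, optionally, at every harmonic below `max_freq`.
#'
#' @param x a [trace()].
#' @param line_freq line frequency in Hz (default 50).
#' @param include_harmonics also notch `2*line_freq, 3*line_freq, ...`?
#' @param max_freq top of the analysis band; harmonics above it (or above
#'   Nyquist) are left alone. Defaults to 300 Hz, the ripple-band top.
#' @param bandwidth -3 dB notch width in Hz.
#' @return a [trace()] of identical length.
#' @export
notch_line <- function(x, line_freq = 50, include_harmonics = TRUE,
                       max_freq = 300, bandwidth = 2) {
  stopifnot(inherits(x, "trace"))
  nyq <- x$fs / 2
  if (line_freq >= nyq) stop("line_freq must be below Nyquist", call. = FALSE)
  freqs <- if (include_harmonics) {
    line_freq * seq_len(floor(min(nyq * 0.99, max_freq) / line_freq))
  } else line_freq
  y <- x$samples
  for (f0 in freqs) {
    ba <- notch_biquad(f0, x$fs, bandwidth)
    filt <- signal::Arma(b = ba$b, a = ba$a)
    pad <- filter_pad_length(x$fs, bandwidth, length(y))
    y <- filtfilt_padded(filt, y, pad)
  }
  with_same_meta(x, y)
}

# standard constrained-poles notch: H(z) = (1 - 2cos(w0) z^-1 + z^-2) /
#   (1 - 2 r cos(w0) z^-1 + r^2 z^-2), r set by the -3 dB bandwidth
notch_biquad <- function(f0, fs, bandwidth) {
  w0 <- 2 * pi * f0 / fs
  r <- 1 - pi * bandwidth / fs          # pole radius ~ exp(-pi*bw/fs)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  # unity gain at DC (and ~unity far from the notch)
  g <- sum(a) / sum(b)
  list(b = b * g, a = a)
}
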