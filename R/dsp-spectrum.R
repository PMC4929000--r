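#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann taper: the trace is cut into
#' `segment_s`-long segments with fractional `overlap`, each segment is
#' detrended (mean removed), tapered and Fourier transformed, and the
#' one-sided densities are averaged. Scaling is such that the integral of
#' the density over frequency approximates the signal variance (Parseval).
#'
#' @param x a [trace()].
#' @param segment_s segment length in seconds (default 1 s, giving ~1 Hz
#'   resolution).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return an object of class `"spectrum_psd"`: `freqs` (Hz), `power`
#'   (units^2/Hz), `method`, `resolution` (Hz).
#' @export
welch_psd <- function(x, segment_s = 1, overlap = 0.5) {
  stopifnot(inherits(x, "trace"))
  nper <- floor(segment_s * x$fs)
  if (nper < 16L) stop("segment must span at least 16 samples", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  if (length(x$samples) < nper)
    stop("trace shorter than one Welch segment", call. = FALSE)
  psd_engine(x$samples, x$fs, nper,
             step = max(1L, floor(nper * (1 - overlap))),
             taper = "hann", method = "welch")
}

#' Averaged-FFT spectrum
#'
#' Mean of periodograms over `n_segments` consecutive, non-overlapping,
#' equal-length segments — the classic "average several consecutive FFTs"
#' estimate used for oscillation peak power and frequency.
#'
#' @param x a [trace()].
#' @param n_segments number of contiguous segments (default 4).
#' @return a `"spectrum_psd"` (see [welch_psd()]) with `method = "fft_avg"`.
#' @export
fft_avg_spectrum <- function(x, n_segments = 4L) {
  stopifnot(inherits(x, "trace"))
  if (n_segments < 1L) stop("n_segments must be >= 1", call. = FALSE)
  nper <- floor(length(x$samples) / n_segments)
  if (nper < 16L) stop("trace too short for that many segments", call. = FALSE)
  psd_engine(x$samples, x$fs, nper, step = nper, taper = "hann",
             method = "fft_avg")
}

# shared one-sided PSD engine
psd_engine <- function(samples, fs, nper, step, taper, method) {
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  } else rep(1, nper)
  norm <- fs * sum(w^2)
  starts <- seq(1L, length(samples) - nper + 1L, by = step)
  acc <- numeric(nper)
  for (s in starts) {
    seg <- samples[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / (length(starts) * norm)
  # fold to one-sided
  half <- floor(nper / 2) + 1L
  p1 <- pxx[seq_len(half)]
  if (nper %% 2 == 0) {
    p1[2:(half - 1L)] <- 2 * p1[2:(half - 1L)]
  } else {
    p1[2:half] <- 2 * p1[2:half]
  }
  structure(
    list(freqs = (seq_len(half) - 1L) * fs / nper, power = p1,
         method = method, resolution = fs / nper),
    class = "spectrum_psd"
  )
}

#' @export
print.spectrum_psd <- function(x, ...) {
  cat(sprintf("<spectrum:%s> %d bins, 0-%.1f Hz, resolution %.3g Hz\n",
              x$method, length(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' Peak frequency and power within a band
#'
#' Returns the frequency and density of the maximal bin inside `band`.
#' Exact ties are broken toward the lower frequency and flagged.
#'
#' @param spec a `"spectrum_psd"`.
#' @param band numeric length-2 `(low, high)` Hz.
#' @return list with `peak_freq` (Hz), `peak_power` (units^2/Hz), `tie`
#'   (logical).
#' @export
spectral_peak <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum_psd"), length(band) == 2L)
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(keep)) stop("band does not intersect the spectrum", call. = FALSE)
  f <- spec$freqs[keep]; p <- spec$power[keep]
  i <- which.max(p)                       # which.max takes the first maximum
  list(peak_freq = f[i], peak_power = p[i],
       tie = sum(p == p[i]) > 1L)
}

#' Band-integrated power
#'
#' Trapezoidal integral of the density over a band; emitted alongside peak
#' power as a diagnostic exposure measure.
#'
#' @inheritParams spectral_peak
#' @return power in units^2.
#' @export
band_power <- function(spec, band) {
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (sum(keep) < 2L) stop("band too narrow for this resolution", call. = FALSE)
  trapz(spec$freqs[keep], spec$power[keep])
}

# trapezoidal rule
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2
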