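#' Find contiguous oscillation epochs in a band
#'
#' Band-limits the trace, rectifies it, low-passes the envelope at 1 Hz and
#' thresholds it at `median + power_k * 1.4826 * MAD`. Contiguous
#' supra-threshold runs of at least `min_len` seconds are returned. Because
#' the threshold is defined from the envelope's own robust statistics,
#' detection is invariant to overall amplitude scaling. When explicit epoch
#' annotations are available (e.g. drug application or running periods),
#' pass them via `epochs` and detection is bypassed.
#'
#' @param x a raw [trace()].
#' @param band oscillation band, Hz (default gamma, 25-90).
#' @param power_k threshold multiplier (default 3).
#' @param min_len minimum epoch length, s (default 10).
#' @param epochs optional data frame `t_start,t_end` of explicit epochs,
#'   returned verbatim.
#' @return data frame `t_start,t_end` (half-open, s).
#' @export
find_oscillation_epochs <- function(x, band = c(25, 90), power_k = 3,
                                    min_len = 10, epochs = NULL) {
  if (!is.null(epochs)) return(as.data.frame(epochs)[c("t_start", "t_end")])
  stopifnot(inherits(x, "trace"))
  bl <- bandpass(x, band[1], band[2])
  env <- abs(bl$samples)
  lp <- signal::butter(2, 1 / (x$fs / 2), type = "low")
  env <- filtfilt_padded(lp, env, filter_pad_length(x$fs, 1, length(env)))
  thr <- stats::median(env) + power_k * stats::mad(env)
  runs <- rle(env > thr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_len * x$fs)
  data.frame(
    t_start = x$t0 + (starts[keep] - 1L) / x$fs,
    t_end = x$t0 + ends[keep] / x$fs
  )
}

#' Characterize a gamma (or theta) epoch
#'
#' Extracts peak frequency and peak spectral density of the epoch within
#' `band`, via Welch or averaged-FFT spectra, and forms the
#' power-by-duration exposure metric used to relate gamma episodes to
#' subsequent SWR changes. Band-integrated power is attached as a
#' diagnostic.
#'
#' @param x a raw [trace()].
#' @param epoch numeric `(t_start, t_end)` in seconds; at least 2 s.
#' @param band analysis band, Hz.
#' @param method `"welch"` (default) or `"fft_avg"`.
#' @param ... passed to [welch_psd()] or [fft_avg_spectrum()].
#' @return one-row data frame `t_start,t_end,peak_freq,peak_power,duration,
#'   power_x_duration,band_power`.
#' @export
characterize_epoch <- function(x, epoch, band = c(25, 90),
                               method = c("welch", "fft_avg"), ...) {
  method <- match.arg(method)
  stopifnot(length(epoch) == 2L)
  if (diff(epoch) < 2) stop("epoch shorter than 2 s", call. = FALSE)
  seg <- trace_window(x, epoch[1], epoch[2])
  spec <- if (method == "welch") welch_psd(seg, ...) else
    fft_avg_spectrum(seg, ...)
  pk <- spectral_peak(spec, band)
  dur <- epoch[2] - epoch[1]
  data.frame(
    t_start = epoch[1], t_end = epoch[2],
    peak_freq = pk$peak_freq, peak_power = pk$peak_power,
    duration = dur, power_x_duration = pk$peak_power * dur,
    band_power = band_power(spec, band)
  )
}

#' Compare two characterized gamma epochs
#'
#' Percentage change in peak power and absolute change in peak frequency,
#' e.g. between a weak gamma episode before and after an intervening strong
#' one.
#'
#' @param first,second one-row data frames from [characterize_epoch()],
#'   characterized with identical settings.
#' @return list `power_change_pct`, `freq_change_hz`.
#' @export
compare_weak_gamma <- function(first, second) {
  if (first$peak_power == 0)
    stop("first epoch has zero peak power; percentage change undefined",
         call. = FALSE)
  list(
    power_change_pct = 100 * (second$peak_power - first$peak_power) /
      first$peak_power,
    freq_change_hz = second$peak_freq - first$peak_freq
  )
}
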