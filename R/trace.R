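#' Uniformly sampled voltage or current trace
#'
#' The universal signal carrier of the package: a numeric vector of samples
#' together with its sampling rate, start time, units and a free-text label.
#' Sample `i` (0-based) sits at time `t0 + i/fs`; all event intervals in the
#' package are half-open `[t_start, t_end)` in seconds.
#'
#' @param samples numeric vector of amplitudes (mV for LFP, pA for current).
#'   Must be finite and of length >= 2.
#' @param fs sampling rate in Hz, > 0.
#' @param t0 start time of the first sample in seconds.
#' @param units `"mV"` or `"pA"`.
#' @param label free-text channel label.
#' @return an object of class `"trace"`.
#' @examples
#' tr <- trace(sin(2 * pi * 10 * seq(0, 1, by = 1e-4)), fs = 1e4)
#' trace_duration(tr)
#' @export
trace <- function(samples, fs, t0 = 0, units = c("mV", "pA"), label = "") {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop(sprintf("non-finite sample at index %d (first of %d)",
                 bad[1L], length(bad)), call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
         units = units, label = as.character(label)[1L]),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz (%.3f s), units %s%s\n",
              length(x$samples), x$fs, trace_duration(x), x$units,
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$samples)

#' Duration of a trace in seconds
#' @param x a [trace()].
#' @return numeric scalar, `length(x)/fs`.
#' @export
trace_duration <- function(x) length(x$samples) / x$fs

#' Time stamps of every sample
#' @param x a [trace()].
#' @return numeric vector `t0 + (0:(n-1))/fs`.
#' @export
trace_times <- function(x) x$t0 + (seq_along(x$samples) - 1L) / x$fs

#' Convert a time (s) to the 0-based sample index at or after it
#' @param x a [trace()].
#' @param t time in seconds.
#' @keywords internal
time_to_index <- function(x, t) {
  i <- ceiling((t - x$t0) * x$fs - 1e-9)
  as.integer(pmin(pmax(i, 0), length(x$samples) - 1L))
}

#' Extract the samples of a half-open time window [t_start, t_end)
#' @param x a [trace()].
#' @param t_start,t_end window bounds in seconds.
#' @return a [trace()] holding the window, with `t0` set to the first
#'   retained sample's time.
#' @export
trace_window <- function(x, t_start, t_end) {
  if (t_end <= t_start) stop("empty window: t_end <= t_start", call. = FALSE)
  i0 <- time_to_index(x, t_start)
  i1 <- ceiling((t_end - x$t0) * x$fs - 1e-9) - 1  # last index strictly before t_end
  i1 <- as.integer(min(i1, length(x$samples) - 1L))
  if (i1 <= i0) stop("window too short for this sampling rate", call. = FALSE)
  trace(x$samples[(i0 + 1L):(i1 + 1L)], x$fs, t0 = x$t0 + i0 / x$fs,
        units = x$units, label = x$label)
}

with_same_meta <- function(template, samples) {
  trace(samples, template$fs, template$t0, template$units, template$label)
}
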