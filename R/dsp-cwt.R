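#' Wavelet scale map for the complex Morlet transform
#'
#' Chooses `n_scales` scales whose center frequencies are log-spaced across
#' `band` (linear spacing available), for a complex Morlet wavelet in the
#' "cmor2-1" parameterization: bandwidth parameter B = 2, center frequency
#' C = 1. The scale (in seconds) mapping to center frequency f is C/f.
#'
#' @param band numeric length-2, `(low, high)` in Hz.
#' @param n_scales number of scales (27 for detection, 134 for display).
#' @param fs sampling rate in Hz of the traces the map will be applied to.
#' @param spacing `"log"` (default) or `"linear"` center-frequency spacing.
#' @return an object of class `"scale_map"` with fields `scales` (seconds),
#'   `center_freqs` (Hz, increasing), `n_scales`, `band`, `fs`.
#' @export
scale_map <- function(band = c(100, 300), n_scales = 27L, fs,
                      spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  if (band[2] >= fs / 2)
    stop("band top must be below Nyquist", call. = FALSE)
  cf <- if (spacing == "log") {
    exp(seq(log(band[1]), log(band[2]), length.out = n_scales))
  } else seq(band[1], band[2], length.out = n_scales)
  structure(
    list(scales = morlet_C / cf, center_freqs = cf,
         n_scales = as.integer(n_scales), band = as.numeric(band),
         fs = as.numeric(fs)),
    class = "scale_map"
  )
}

# cmor2-1: bandwidth B = 2, center frequency C = 1
morlet_B <- 2
morlet_C <- 1

# time-domain half support (3 Gaussian SDs) of the wavelet at scale a seconds
morlet_half_support_s <- function(a) 3 * a * sqrt(morlet_B / 2)

#' Complex Morlet continuous wavelet transform
#'
#' Computes coefficients of the complex Morlet wavelet ("cmor2-1":
#' `psi(t) = (pi*B)^(-1/2) exp(2*pi*i*C*t) exp(-t^2/B)` with B = 2, C = 1)
#' at the scales of a [scale_map()]. The transform is evaluated in the
#' frequency domain (the Morlet's Fourier transform is a Gaussian centered
#' at C/a), after reflect-padding the trace by the support of the longest
#' wavelet.
#'
#' @param x a [trace()]; callers normally band-pass it to the map's band
#'   first.
#' @param map a [scale_map()] built for `x$fs`.
#' @return an object of class `"cwt"`: complex matrix `coeffs`
#'   (`n_scales` rows, one column per sample), `times`, and the `map`.
#' @export
morlet_cwt <- function(x, map) {
  stopifnot(inherits(x, "trace"), inherits(map, "scale_map"))
  if (abs(map$fs - x$fs) > 1e-6)
    stop("scale map was built for fs = ", map$fs, ", trace has fs = ", x$fs,
         call. = FALSE)
  n <- length(x$samples)
  max_support <- 2 * morlet_half_support_s(max(map$scales)) # seconds
  if (n / x$fs < max_support)
    stop(sprintf(
      "trace (%.1f ms) shorter than the longest wavelet support (%.1f ms)",
      1000 * n / x$fs, 1000 * max_support), call. = FALSE)

  pad <- min(n - 1L, ceiling(max_support / 2 * x$fs))
  xp <- c(2 * x$samples[1L] - x$samples[(pad + 1L):2L],
          x$samples,
          2 * x$samples[n] - x$samples[(n - 1L):(n - pad)])
  np <- length(xp)
  X <- stats::fft(xp)
  f <- (seq_len(np) - 1L) / np * x$fs
  f[f > x$fs / 2] <- f[f > x$fs / 2] - x$fs   # two-sided frequency grid

  coeffs <- matrix(0i, nrow = map$n_scales, ncol = n)
  for (k in seq_len(map$n_scales)) {
    a <- map$scales[k]
    # L1-normalized scaled wavelet (kernel psi(t/a)/a): its Fourier
    # transform is exp(-pi^2*B*(a*f - C)^2), so a pure tone at C/a gives the
    # same coefficient magnitude at every scale and the scale of maximal
    # response localizes the tone frequency without bias
    H <- exp(-pi^2 * morlet_B * (a * f - morlet_C)^2)
    w <- stats::fft(X * H, inverse = TRUE) / np
    coeffs[k, ] <- w[(pad + 1L):(pad + n)]
  }
  structure(list(coeffs = coeffs, times = trace_times(x), map = map),
            class = "cwt")
}

#' Maximum absolute wavelet coefficient in a time window
#'
#' The detection statistic behind the spectral threshold criterion: the
#' maximum of `|coefficient|` over all scales and all samples whose time
#' falls in the half-open window.
#'
#' @param cw a `"cwt"` object from [morlet_cwt()].
#' @param window numeric length-2 `(t_start, t_end)` in seconds; `NULL`
#'   takes the whole extent.
#' @return a single non-negative number.
#' @export
max_abs_coeff <- function(cw, window = NULL) {
  stopifnot(inherits(cw, "cwt"))
  if (is.null(window)) return(max(Mod(cw$coeffs)))
  stopifnot(length(window) == 2L)
  keep <- cw$times >= window[1] & cw$times < window[2]
  if (!any(keep)) stop("window contains no samples", call. = FALSE)
  max(Mod(cw$coeffs[, keep, drop = FALSE]))
}
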