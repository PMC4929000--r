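#' SWR detection configuration
#'
#' Parameters of the dual-criterion detector. The voltage criterion
#' thresholds the rectified ripple-band trace at `mean + voltage_k * SD` of
#' the event-free recording; the spectral criterion thresholds each
#' candidate's maximum absolute complex-Morlet coefficient against
#' `mean + spectral_k * SD` of the same statistic computed on event-free
#' cutouts preceding the candidates.
#'
#' @param sw_band sharp-wave band, Hz (default 2-50).
#' @param ripple_band ripple band, Hz (default 100-300).
#' @param voltage_k SD multiplier of the voltage threshold (default 6).
#' @param spectral_k SD multiplier of the spectral threshold (default 1).
#' @param cutout_ms length of the event-free cutouts, ms (default 70).
#' @param n_scales wavelet scales of the detection map (default 27).
#' @param group_gap_ms individual ripples closer than this merge into one
#'   candidate event (default 20 ms, about 2-4 ripple cycles).
#' @param min_ripples minimum threshold crossings per candidate (default 3).
#' @param boundary_search_ms local-minima search range around the
#'   sharp-wave peak (default 100 ms each side).
#' @param min_neighborhood_ms a boundary must be a strict minimum over this
#'   neighborhood, suppressing noise minima (default 5 ms).
#' @param baseline_guard_ms guard margin masked around provisional events
#'   when estimating the event-free baseline (default 100 ms).
#' @param filter_order Butterworth order per pass for the band split.
#' @param noise_area_correction subtract the mean area that the same
#'   delimitation + quantification procedure measures on event-free
#'   stretches? Because boundaries sit at local minima, the noise path
#'   enclosed between them integrates positive, adding a small constant to
#'   every event area; the correction removes that constant (floored at
#'   zero). Default `TRUE`.
#' @return a list of class `"detection_config"`.
#' @export
detection_config <- function(sw_band = c(2, 50), ripple_band = c(100, 300),
                             voltage_k = 6, spectral_k = 1,
                             cutout_ms = 70, n_scales = 27L,
                             group_gap_ms = 20, min_ripples = 3L,
                             boundary_search_ms = 100,
                             min_neighborhood_ms = 5,
                             baseline_guard_ms = 100,
                             filter_order = 2L,
                             noise_area_correction = TRUE) {
  stopifnot(voltage_k > 0, spectral_k >= 0, cutout_ms > 0, group_gap_ms > 0,
            min_ripples >= 1L, boundary_search_ms > 0)
  structure(as.list(environment()), class = "detection_config")
}

#' Split a raw LFP trace into sharp-wave and ripple traces
#'
#' Zero-phase Butterworth band-passes into the configured sharp-wave
#' (2-50 Hz) and ripple (100-300 Hz) bands.
#'
#' @param x a [trace()], `fs > 600` Hz.
#' @param config a [detection_config()].
#' @return list with traces `sw` and `ripple`, each the length of `x`.
#' @export
split_bands <- function(x, config = detection_config()) {
  stopifnot(inherits(x, "trace"))
  if (x$fs <= 2 * config$ripple_band[2])
    stop("sampling rate too low: Nyquist must exceed the ripple band top",
         call. = FALSE)
  list(
    sw = bandpass(x, config$sw_band[1], config$sw_band[2],
                  config$filter_order),
    ripple = bandpass(x, config$ripple_band[1], config$ripple_band[2],
                      config$filter_order)
  )
}

#' Estimate event-free baseline statistics of the ripple trace
#'
#' Two-pass procedure: pass 1 masks provisional events where the rectified
#' ripple trace exceeds a robust threshold (`median + voltage_k * 1.4826 *
#' MAD`), expanded by a guard margin; pass 2 computes the mean and SD of the
#' ripple trace over the unmasked (event-free) remainder. The voltage
#' threshold `mean + voltage_k * SD` is later applied to the rectified
#' trace. Both detection thresholds are defined relative to these
#' statistics, which makes the whole detector invariant to amplitude
#' rescaling.
#'
#' @param ripple a ripple-band [trace()] of at least 10 s.
#' @param config a [detection_config()].
#' @return list of class `"baseline_stats"`: `mean`, `sd`, `n_samples`,
#'   `mask` (TRUE = event-free), `fs`.
#' @export
estimate_baseline <- function(ripple, config = detection_config()) {
  stopifnot(inherits(ripple, "trace"))
  if (trace_duration(ripple) < 10)
    stop("baseline estimation needs at least 10 s of recording", call. = FALSE)
  r <- abs(ripple$samples)
  med <- stats::median(r)
  madv <- stats::mad(r)                       # 1.4826 * median abs deviation
  if (madv == 0 && stats::sd(r) == 0)
    stop("degenerate baseline: ripple trace is constant", call. = FALSE)
  thr1 <- med + config$voltage_k * madv
  guard <- round(config$baseline_guard_ms / 1000 * ripple$fs)
  mask <- !expand_runs(r > thr1, guard)
  if (sum(mask) < ripple$fs)
    stop("event-free region shorter than 1 s; supply a manual baseline",
         call. = FALSE)
  structure(
    list(mean = mean(ripple$samples[mask]), sd = stats::sd(ripple$samples[mask]),
         n_samples = sum(mask), mask = mask, fs = ripple$fs,
         t0 = ripple$t0),
    class = "baseline_stats"
  )
}

# expand TRUE runs of a logical vector by `pad` samples on each side
expand_runs <- function(flag, pad) {
  if (!any(flag) || pad <= 0) return(flag)
  rl <- rle(flag)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  out <- logical(length(flag))
  for (k in which(rl$values)) {
    out[max(1L, starts[k] - pad):min(length(flag), ends[k] + pad)] <- TRUE
  }
  out
}

#' Voltage-threshold candidate detection on the ripple trace
#'
#' Applies `mean + voltage_k * SD` of the event-free baseline to the
#' rectified ripple trace. Contiguous supra-threshold runs separated by at
#' most `group_gap_ms` are grouped into one candidate event; candidates
#' with fewer than `min_ripples` supra-threshold rectified peaks (one per
#' ripple half-wave) are discarded.
#'
#' @param ripple a ripple-band [trace()].
#' @param baseline a `"baseline_stats"` from [estimate_baseline()].
#' @param config a [detection_config()].
#' @return data frame `t_start,t_end,n_crossings` of sorted, non-overlapping
#'   half-open candidate intervals.
#' @export
detect_ripple_candidates <- function(ripple, baseline,
                                     config = detection_config()) {
  stopifnot(inherits(ripple, "trace"), inherits(baseline, "baseline_stats"))
  thr <- baseline$mean + config$voltage_k * baseline$sd
  supra <- abs(ripple$samples) > thr
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      n_crossings = integer(0))
  if (!any(supra)) return(empty)
  rl <- rle(supra)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  ri <- which(rl$values)
  rs <- starts[ri]; re <- ends[ri]            # individual ripple runs
  gap_n <- config$group_gap_ms / 1000 * ripple$fs
  new_grp <- c(TRUE, (rs[-1] - re[-length(re)] - 1L) > gap_n)
  grp <- cumsum(new_grp)
  g_start <- as.integer(tapply(rs, grp, min))
  g_end <- as.integer(tapply(re, grp, max))
  # individual ripples are counted as supra-threshold peaks of the
  # rectified trace (one per half-wave); unlike raw run counts this is
  # insensitive to whether consecutive half-waves share a threshold run
  r <- abs(ripple$samples)
  pk <- which(supra & r >= c(-Inf, r[-length(r)]) & r > c(r[-1], -Inf))
  n_peaks <- findInterval(g_end, pk) - findInterval(g_start - 1L, pk)
  cand <- data.frame(
    t_start = ripple$t0 + (g_start - 1L) / ripple$fs,
    t_end = ripple$t0 + g_end / ripple$fs,
    n_crossings = as.integer(n_peaks)
  )
  cand <- cand[cand$n_crossings >= config$min_ripples, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# max |CWT coefficient| over [t0, t1), computed on a context segment so that
# windows shorter than the longest wavelet's support still work
cwt_max_in_window <- function(x, t0, t1, map) {
  pad_s <- morlet_half_support_s(max(map$scales)) * 1.2
  seg <- trace_window(x, max(x$t0, t0 - pad_s),
                      min(x$t0 + trace_duration(x), t1 + pad_s))
  cw <- morlet_cwt(seg, map)
  max_abs_coeff(cw, c(t0, t1))
}

#' Spectral validation of ripple candidates
#'
#' For each candidate, takes the `cutout_ms` event-free cutout immediately
#' preceding it (skipping back over masked samples of other events),
#' computes the maximum absolute complex-Morlet coefficient of every cutout
#' (27-scale map over the ripple band), and accepts a candidate only if its
#' own maximum coefficient exceeds `mean + spectral_k * SD` of the cutout
#' distribution. Rejected candidates are retained with
#' `rejection_reason = "spectral"`. Candidates for which no event-free
#' cutout exists are flagged in `cutout_found` and judged against the same
#' threshold. When fewer than 3 candidate-preceding cutouts exist (sparse
#' recordings), the distribution is supplemented with additional
#' non-overlapping event-free windows spread across the trace.
#'
#' @param ripple a ripple-band [trace()].
#' @param candidates data frame from [detect_ripple_candidates()].
#' @param baseline a `"baseline_stats"` (its mask defines "event-free").
#' @param config a [detection_config()].
#' @return `candidates` with columns `max_abs_coeff`, `cutout_coeff`,
#'   `cutout_found`, `accepted`, `rejection_reason`, plus attribute
#'   `spectral_threshold`.
#' @export
spectral_validate <- function(ripple, candidates, baseline,
                              config = detection_config()) {
  stopifnot(inherits(ripple, "trace"))
  n_cand <- nrow(candidates)
  out <- candidates
  out$max_abs_coeff <- numeric(n_cand)
  out$cutout_coeff <- rep(NA_real_, n_cand)
  out$cutout_found <- logical(n_cand)
  if (n_cand == 0L) {
    out$accepted <- logical(0)
    out$rejection_reason <- character(0)
    attr(out, "spectral_threshold") <- NA_real_
    return(out)
  }
  map <- scale_map(config$ripple_band, config$n_scales, ripple$fs)
  L <- round(config$cutout_ms / 1000 * ripple$fs)
  # positions where a full event-free window of length L ends (1-based index)
  cmask <- cumsum(baseline$mask)
  valid_end <- which(seq_along(baseline$mask) >= L &
                       (cmask - c(rep(0, L), utils::head(cmask, -L))) == L)
  for (i in seq_len(n_cand)) {
    s_idx <- time_to_index(ripple, candidates$t_start[i]) + 1L
    j <- valid_end[findInterval(s_idx - 1L, valid_end)]
    if (length(j) == 1L && !is.na(j)) {
      c_t1 <- ripple$t0 + j / ripple$fs
      c_t0 <- c_t1 - L / ripple$fs
      out$cutout_coeff[i] <- cwt_max_in_window(ripple, c_t0, c_t1, map)
      out$cutout_found[i] <- TRUE
    }
    out$max_abs_coeff[i] <- cwt_max_in_window(
      ripple, candidates$t_start[i], candidates$t_end[i], map)
  }
  cut <- out$cutout_coeff[out$cutout_found]
  if (length(cut) < 3L) {
    # sparse recordings: supplement the cutout distribution with additional
    # non-overlapping event-free windows spread over the trace, so the
    # threshold is still estimated from >= 3 cutouts
    extra_ends <- integer(0)
    last <- -Inf
    for (j in valid_end) {
      if (j - last >= L) { extra_ends <- c(extra_ends, j); last <- j }
    }
    extra_ends <- extra_ends[!extra_ends %in%
                               valid_end[findInterval(
                                 time_to_index(ripple, candidates$t_start),
                                 valid_end)]]
    if (length(extra_ends) > 20L)
      extra_ends <- extra_ends[round(seq(1, length(extra_ends),
                                         length.out = 20L))]
    extra <- vapply(extra_ends, function(j) {
      c_t1 <- ripple$t0 + j / ripple$fs
      cwt_max_in_window(ripple, c_t1 - L / ripple$fs, c_t1, map)
    }, numeric(1))
    cut <- c(cut, extra)
  }
  if (length(cut) < 3L)
    stop("fewer than 3 event-free cutouts available for the spectral ",
         "threshold", call. = FALSE)
  thr <- mean(cut) + config$spectral_k * stats::sd(cut)
  out$accepted <- out$max_abs_coeff > thr
  out$rejection_reason <- ifelse(out$accepted, "none", "spectral")
  attr(out, "spectral_threshold") <- thr
  out
}

#' Delimit an SWR at the flanking sharp-wave local minima
#'
#' From the sharp-wave peak inside the candidate interval (the extremum of
#' the dominant deflection; its sign defines the event polarity), walks
#' outward to the nearest strict local minima of the polarity-aligned
#' sharp-wave trace within `boundary_search_ms`. A boundary qualifies only
#' if it is the strict minimum of a `min_neighborhood_ms` neighborhood. If
#' no minimum exists on a side, the boundary is set at the search-window
#' edge and the event is flagged.
#'
#' @param sw a sharp-wave band [trace()].
#' @param interval numeric `(t_start, t_end)` of the candidate.
#' @param config a [detection_config()].
#' @return list `t_start`, `t_end` (half-open, s), `polarity` (+1/-1),
#'   `peak_t` (s), `flagged` (logical: window-edge boundary used).
#' @export
delimit_event <- function(sw, interval, config = detection_config()) {
  stopifnot(inherits(sw, "trace"), length(interval) == 2L)
  fs <- sw$fs
  n <- length(sw$samples)
  i0 <- time_to_index(sw, interval[1]) + 1L
  i1 <- time_to_index(sw, interval[2]) + 1L
  if (i1 <= i0) stop("degenerate candidate interval", call. = FALSE)
  seg <- sw$samples[i0:i1]
  pol <- if (max(seg) >= -min(seg)) 1 else -1
  y_all <- pol * sw$samples
  p <- i0 - 1L + which.max(seg * pol)

  search_n <- round(config$boundary_search_ms / 1000 * fs)
  w <- max(1L, round(config$min_neighborhood_ms / 1000 * fs / 2))
  lo <- max(1L, p - search_n - w)
  hi <- min(n, p + search_n + w)
  mins <- strict_local_minima(y_all[lo:hi], w) + lo - 1L
  left <- mins[mins < p & mins >= p - search_n]
  right <- mins[mins > p & mins <= p + search_n]
  flagged <- FALSE
  if (length(left)) b0 <- max(left) else { b0 <- max(1L, p - search_n); flagged <- TRUE }
  if (length(right)) b1 <- min(right) else { b1 <- min(n, p + search_n); flagged <- TRUE }
  # reference level at each boundary: the neighborhood median is unbiased
  # under noise, unlike the minimum sample itself, which sits about one
  # noise SD low and would inflate every chord-referenced area
  nb_med <- function(b) stats::median(
    sw$samples[max(1L, b - w):min(n, b + w)])
  list(t_start = sw$t0 + (b0 - 1L) / fs,
       t_end = sw$t0 + b1 / fs,            # half-open: include b1
       polarity = pol, peak_t = sw$t0 + (p - 1L) / fs, flagged = flagged,
       ref_start = nb_med(b0), ref_end = nb_med(b1))
}

# indices that are strict minima of y over a +-w neighborhood
strict_local_minima <- function(y, w) {
  n <- length(y)
  if (n < 2L * w + 1L) return(integer(0))
  M <- stats::embed(y, 2L * w + 1L)          # rows: windows, reversed order
  rmin <- do.call(pmin, as.data.frame(M))
  cnt <- rowSums(M == rmin)
  centers <- seq_len(n - 2L * w) + w         # center index of each window
  centers[M[, w + 1L] == rmin & cnt == 1L]
}

#' Quantify a delimited SWR event
#'
#' Area is the trapezoidal integral of the sharp-wave trace over the
#' half-open event interval, measured relative to the chord joining the
#' trace values at the start and end points (the flanking minima) and
#' reported as the magnitude of the event-polarity deflection (mV*s).
#' Referencing the chord rather than a global level cancels any slow local
#' baseline shift — in particular the shallow sag the 2 Hz high-pass
#' spreads between events, whose depth tracks the local event rate and
#' amplitude. Amplitude is the peak deflection above the chord, duration
#' the interval length. Ripple cycles are counted as supra-threshold local
#' maxima of the signed ripple trace (one per cycle); ripple frequency is
#' `(count - 1) / (time between first and last counted peak)`, reported
#' only when at least two peaks exist.
#'
#' @param sw,ripple band-split [trace()]s.
#' @param event a delimitation as returned by [delimit_event()].
#' @param baseline a `"baseline_stats"`; supplies the voltage threshold for
#'   ripple-peak counting.
#' @param config a [detection_config()].
#' @param sw_level optional fixed baseline level; when supplied it replaces
#'   the chord reference (useful for traces with a known flat baseline).
#' @return one-row data frame with the standard event columns (without
#'   `accepted`/`rejection_reason`, which detection fills in).
#' @export
quantify_event <- function(sw, ripple, event, baseline,
                           config = detection_config(), sw_level = NULL) {
  stopifnot(inherits(sw, "trace"))
  i0 <- time_to_index(sw, event$t_start) + 1L
  i1 <- time_to_index(sw, event$t_end) + 1L
  if (i1 - i0 < 2L) stop("degenerate event interval", call. = FALSE)
  idx <- i0:(i1 - 1L)                         # half-open [t_start, t_end)
  ref <- if (!is.null(sw_level)) {
    rep(sw_level, length(idx))
  } else {
    # chord through the boundary reference levels; [delimit_event()]
    # supplies noise-robust neighborhood medians, otherwise the boundary
    # samples themselves are used
    r0 <- if (!is.null(event$ref_start)) event$ref_start else sw$samples[i0]
    r1 <- if (!is.null(event$ref_end)) event$ref_end else sw$samples[i1]
    seq(r0, r1, length.out = i1 - i0 + 1L)[seq_len(i1 - i0)]
  }
  y <- event$polarity * (sw$samples[idx] - ref)
  tt <- sw$t0 + (idx - 1L) / sw$fs
  area <- abs(trapz(tt, y))
  amp <- max(y)

  thr <- if (!is.null(baseline))
    baseline$mean + config$voltage_k * baseline$sd else 0
  r <- ripple$samples[idx]
  pk <- which(r > thr &
                r >= c(-Inf, r[-length(r)]) &
                r > c(r[-1], -Inf))
  ripple_count <- length(pk)
  ripple_freq <- if (ripple_count >= 2L) {
    (ripple_count - 1L) / ((pk[ripple_count] - pk[1L]) / sw$fs)
  } else NA_real_
  data.frame(
    t_start = event$t_start, t_end = event$t_end,
    area = area, sw_amplitude = amp,
    duration_ms = (event$t_end - event$t_start) * 1000,
    ripple_count = ripple_count, ripple_freq = ripple_freq
  )
}

#' Detect and quantify sharp wave-ripples in an LFP trace
#'
#' The full pipeline: band split (2-50 / 100-300 Hz), event-free baseline
#' estimation, voltage-threshold candidate detection with ripple grouping,
#' Morlet spectral validation, local-minima delimitation and per-event
#' quantification. Manual curation — the programmatic stand-in for visual
#' scrutiny — is applied last from an edit table.
#'
#' @param x a raw LFP [trace()].
#' @param config a [detection_config()].
#' @param curation optional data frame with columns
#'   `event_index, action, t_start, t_end`; `action` is one of `"accept"`,
#'   `"reject"`, `"set_bounds"`. Indices refer to the uncurated output
#'   order.
#' @return data frame of events, sorted by `t_start`, with columns
#'   `t_start,t_end,area,sw_amplitude,duration_ms,ripple_count,ripple_freq,
#'   max_abs_coeff,accepted,rejection_reason` (plus `polarity`,
#'   `cutout_found`). Attributes carry the `baseline` and
#'   `spectral_threshold`.
#' @export
detect_swr <- function(x, config = detection_config(), curation = NULL) {
  bands <- split_bands(x, config)
  baseline <- tryCatch(estimate_baseline(bands$ripple, config),
                       error = function(e)
                         stop("baseline stage: ", conditionMessage(e),
                              call. = FALSE))
  cand <- detect_ripple_candidates(bands$ripple, baseline, config)
  if (nrow(cand) == 0L) {
    ev <- empty_events()
  } else {
    val <- spectral_validate(bands$ripple, cand, baseline, config)
    rows <- vector("list", nrow(val))
    for (i in seq_len(nrow(val))) {
      d <- delimit_event(bands$sw, c(val$t_start[i], val$t_end[i]), config)
      q <- quantify_event(bands$sw, bands$ripple, d, baseline, config)
      q$max_abs_coeff <- val$max_abs_coeff[i]
      q$accepted <- val$accepted[i]
      q$rejection_reason <- if (!val$accepted[i]) "spectral"
                            else if (d$flagged) "boundary" else "none"
      q$polarity <- d$polarity
      q$cutout_found <- val$cutout_found[i]
      rows[[i]] <- q
    }
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$t_start), , drop = FALSE]
    rownames(ev) <- NULL
    attr(ev, "spectral_threshold") <- attr(val, "spectral_threshold")
    if (isTRUE(config$noise_area_correction)) {
      delta <- chord_bias_estimate(bands$sw, baseline, config)
      if (is.finite(delta) && delta > 0) {
        ev$area <- pmax(0, ev$area - delta * (ev$t_end - ev$t_start))
        attr(ev, "chord_bias") <- delta
      }
    }
  }
  if (!is.null(curation) && nrow(ev) > 0L)
    ev <- apply_curation(ev, curation, bands, baseline, config)
  attr(ev, "baseline") <- baseline
  ev
}

# Expected depth of a boundary reference below the local baseline level.
# Event boundaries are strict local minima, so their neighborhood medians
# sit below the event-free mean by some delta > 0; the chord through them
# then adds a slab of delta * duration to every event area. delta is
# estimated from strict local minima on event-free stretches.
chord_bias_estimate <- function(sw, baseline, config, max_segments = 30L) {
  fs <- sw$fs
  w <- max(1L, round(config$min_neighborhood_ms / 1000 * fs / 2))
  seg_n <- round(fs)                          # 1 s segments
  rl <- rle(baseline$mask)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  ok <- which(rl$values & rl$lengths >= seg_n)
  if (!length(ok)) return(NA_real_)
  seg_starts <- unlist(lapply(ok, function(k)
    seq(starts[k], ends[k] - seg_n + 1L, by = seg_n)))
  if (length(seg_starts) > max_segments)
    seg_starts <- seg_starts[round(seq(1, length(seg_starts),
                                       length.out = max_segments))]
  refs <- unlist(lapply(seg_starts, function(s) {
    y <- sw$samples[s:(s + seg_n - 1L)]
    mins <- strict_local_minima(y, w)
    vapply(mins, function(b)
      stats::median(y[max(1L, b - w):min(seg_n, b + w)]), numeric(1))
  }))
  if (length(refs) < 10L) return(NA_real_)
  mean(sw$samples[baseline$mask]) - mean(refs)   # > 0: refs sit low
}

empty_events <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0), area = numeric(0),
             sw_amplitude = numeric(0), duration_ms = numeric(0),
             ripple_count = integer(0), ripple_freq = numeric(0),
             max_abs_coeff = numeric(0), accepted = logical(0),
             rejection_reason = character(0), polarity = numeric(0),
             cutout_found = logical(0))
}

apply_curation <- function(ev, curation, bands, baseline, config) {
  needed <- c("event_index", "action")
  if (!all(needed %in% names(curation)))
    stop("curation table needs columns event_index and action", call. = FALSE)
  for (k in seq_len(nrow(curation))) {
    i <- curation$event_index[k]
    if (i < 1L || i > nrow(ev))
      stop("curation refers to nonexistent event ", i, call. = FALSE)
    act <- curation$action[k]
    if (act == "accept") {
      ev$accepted[i] <- TRUE
      ev$rejection_reason[i] <- "none"
    } else if (act == "reject") {
      ev$accepted[i] <- FALSE
      ev$rejection_reason[i] <- "manual"
    } else if (act == "set_bounds") {
      d <- list(t_start = curation$t_start[k], t_end = curation$t_end[k],
                polarity = ev$polarity[i], flagged = FALSE)
      q <- quantify_event(bands$sw, bands$ripple, d, baseline, config)
      ev[i, names(q)] <- q
      ev$rejection_reason[i] <- "none"
    } else stop("unknown curation action: ", act, call. = FALSE)
  }
  ev
}
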