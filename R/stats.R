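#' Pre/post-gamma analysis windows
#'
#' Windowing convention for paired comparisons: a `pre_len`-second window
#' ending `pre_end_offset` seconds before gamma onset and a
#' `post_len`-second window starting `post_start_offset` seconds after
#' gamma offset (defaults: 120 s windows ending 10 s before and starting
#' 30 s after the episode).
#'
#' @param pre_len,post_len window lengths, s.
#' @param pre_end_offset gap between the pre window and gamma onset, s.
#' @param post_start_offset gap between gamma offset and the post window, s.
#' @return list of class `"window_spec"`.
#' @export
window_spec <- function(pre_len = 120, post_len = 120,
                        pre_end_offset = 10, post_start_offset = 30) {
  stopifnot(pre_len > 0, post_len > 0, pre_end_offset >= 0,
            post_start_offset >= 0)
  structure(as.list(environment()), class = "window_spec")
}

#' Place the pre and post windows around a gamma epoch
#'
#' @param gamma_epoch numeric `(t_start, t_end)` of the gamma episode, s.
#' @param spec a [window_spec()].
#' @param trace_extent numeric `(t_min, t_max)` of the recording, s.
#' @return list with `pre` and `post`, each `(t_start, t_end)` half-open.
#' @export
make_windows <- function(gamma_epoch, spec = window_spec(),
                         trace_extent) {
  stopifnot(length(gamma_epoch) == 2L, length(trace_extent) == 2L)
  pre <- c(gamma_epoch[1] - spec$pre_end_offset - spec$pre_len,
           gamma_epoch[1] - spec$pre_end_offset)
  post <- c(gamma_epoch[2] + spec$post_start_offset,
            gamma_epoch[2] + spec$post_start_offset + spec$post_len)
  if (pre[1] < trace_extent[1] - 1e-9)
    stop(sprintf("recording starts %.1f s too late for the pre window",
                 trace_extent[1] - pre[1]), call. = FALSE)
  if (post[2] > trace_extent[2] + 1e-9)
    stop(sprintf("recording ends %.1f s too early for the post window",
                 post[2] - trace_extent[2]), call. = FALSE)
  list(pre = pre, post = post)
}

#' Summarize accepted SWR events inside a window
#'
#' @param events event data frame (from [detect_swr()] or ground truth with
#'   an `area` column); only rows with `accepted == TRUE` (or all rows if no
#'   `accepted` column) are used.
#' @param window numeric `(t_start, t_end)`, half-open.
#' @return one-row data frame `n,incidence,mean_area,mean_ripple_count,
#'   mean_ripple_freq,mean_amplitude,mean_duration_ms,empty`. An empty
#'   window has `incidence = 0` and `NA` means, flagged by `empty`.
#' @export
summarize_window <- function(events, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  ev <- as.data.frame(events)
  if ("accepted" %in% names(ev)) ev <- ev[ev$accepted, , drop = FALSE]
  ev <- ev[ev$t_start >= window[1] & ev$t_start < window[2], , drop = FALSE]
  n <- nrow(ev)
  len <- window[2] - window[1]
  m <- function(col) if (n > 0 && col %in% names(ev))
    mean(ev[[col]], na.rm = TRUE) else NA_real_
  data.frame(
    n = n, incidence = n / len, mean_area = m("area"),
    mean_ripple_count = m("ripple_count"),
    mean_ripple_freq = m("ripple_freq"),
    mean_amplitude = m("sw_amplitude"),
    mean_duration_ms = m("duration_ms"),
    empty = n == 0L
  )
}

#' Exact Wilcoxon signed-rank test
#'
#' Signed-rank statistic with average ranks for tied absolute differences
#' and the drop-zeros convention for zero differences. For `n <=
#' exact_limit` the two-sided p-value comes from the exact permutation null
#' — the distribution of the statistic over all `2^n` sign assignments,
#' computed by convolution of the rank generating polynomial, which is
#' exact for tied ranks too. Larger `n` uses the normal approximation with
#' continuity correction.
#'
#' @param d numeric vector of paired differences.
#' @param exact_limit maximum `n` for the exact null (default 25).
#' @return list `statistic` (V, rank sum of positive differences),
#'   `p_value` (two-sided), `n` (non-zero pairs), `n_zero` (dropped),
#'   `exact`, `degenerate` (all differences zero).
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 25L) {
  d <- as.numeric(d)
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p_value = 1, n = 0L, n_zero = n_zero,
                exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of 2V over all sign assignments, by convolution of the
    # generating polynomial prod_i (1 + z^(2*r_i)); 2r is integer even with
    # average ranks, so this is exact under ties too
    r2 <- as.integer(round(2 * r))
    counts <- 1                              # counts[k+1] = #assignments with 2V = k
    for (ri in r2) counts <- c(counts, numeric(ri)) + c(numeric(ri), counts)
    v2 <- round(2 * v)
    total <- 2^n
    p_le <- sum(counts[seq_len(v2 + 1L)]) / total
    p_ge <- sum(counts[(v2 + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu - sign(v - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = v, p_value = p, n = n, n_zero = n_zero, exact = exact,
       degenerate = FALSE)
}

#' Paired pre/post comparison
#'
#' The machinery behind every pre/post-gamma statistic: normalization of
#' the post values to the mean of the pre values, percentage change,
#' standard error, and a paired test — exact Wilcoxon signed-rank (default,
#' see [wilcoxon_signed_rank()]) or the paired Student's t-test.
#'
#' @param pre,post paired numeric vectors of equal length.
#' @param test `"wilcoxon"` or `"t_paired"`.
#' @param metric_name label carried through to the result.
#' @return list of class `"session_comparison"`: `metric_name`,
#'   `pre_values`, `post_values`, `normalized_post` (post / mean(pre)),
#'   `pct_change` (100 * (mean(post) - mean(pre)) / mean(pre)), `sem` (SEM
#'   of the per-pair percentage changes), `test_name`, `statistic`,
#'   `p_value`, `n`, `n_zero_dropped`, `degenerate`.
#' @export
paired_compare <- function(pre, post, test = c("wilcoxon", "t_paired"),
                           metric_name = "") {
  test <- match.arg(test)
  stopifnot(length(pre) == length(post), length(pre) >= 1L)
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 1L) stop("no complete pairs", call. = FALSE)
  mp <- mean(pre)
  if (mp == 0) stop("zero pre mean: percentage change undefined",
                    call. = FALSE)
  d <- post - pre
  if (test == "wilcoxon") {
    w <- wilcoxon_signed_rank(d)
    statistic <- w$statistic; p <- w$p_value
    n_zero <- w$n_zero; degenerate <- w$degenerate
  } else {
    degenerate <- stats::sd(d) == 0
    n_zero <- 0L
    if (degenerate) {
      statistic <- NA_real_; p <- 1
    } else {
      tt <- stats::t.test(post, pre, paired = TRUE)
      statistic <- unname(tt$statistic); p <- tt$p.value
    }
  }
  per_pair_pct <- 100 * d / pre
  structure(
    list(metric_name = metric_name, pre_values = pre, post_values = post,
         normalized_post = post / mp,
         pct_change = 100 * (mean(post) - mp) / mp,
         sem = stats::sd(per_pair_pct) / sqrt(n),
         test_name = test, statistic = statistic, p_value = p, n = n,
         n_zero_dropped = n_zero, degenerate = degenerate),
    class = "session_comparison"
  )
}

#' @export
print.session_comparison <- function(x, ...) {
  cat(sprintf(
    "<%s> n = %d: %+.1f%% (SEM %.1f), %s p = %.4g%s\n",
    if (nzchar(x$metric_name)) x$metric_name else "comparison",
    x$n, x$pct_change, x$sem, x$test_name, x$p_value,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Normalize a series to the mean of its pre-gamma values
#'
#' @param values numeric vector.
#' @param pre_mask logical vector marking pre-gamma entries (>= 1 TRUE).
#' @return `values / mean(values[pre_mask])`; the normalized pre values
#'   average exactly 1.
#' @export
normalize_series <- function(values, pre_mask) {
  stopifnot(length(values) == length(pre_mask))
  if (!any(pre_mask)) stop("pre_mask selects no values", call. = FALSE)
  m <- mean(values[pre_mask])
  if (m == 0) stop("zero pre-gamma mean: normalization undefined",
                   call. = FALSE)
  values / m
}

#' Spearman rank correlation with permutation p-value
#'
#' Spearman's rho with average ranks for ties. For `n <= exact_limit` the
#' two-sided p-value is exact: the proportion of all `n!` permutations with
#' `|rho| >=` the observed. Larger `n` uses the t-approximation.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @param exact_limit maximum `n` for full enumeration (default 9).
#' @return list `rho`, `p_value`, `n`, `exact`, `constant_input` (rho is
#'   `NA` when either input is constant).
#' @export
correlate <- function(x, y, exact_limit = 9L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, exact = NA,
                constant_input = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    P <- perm_matrix(n)
    # rho over permutations of the y ranks against fixed x ranks
    ryp <- matrix(ry[P], nrow = nrow(P))
    num <- ryp %*% rx - n * mean(rx) * mean(ry)
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    rho_perm <- as.numeric(num) / den
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    exact <- FALSE
  }
  list(rho = rho, p_value = p, n = n, exact = exact, constant_input = FALSE)
}

# all permutations of 1..n, one per row
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perm_matrix(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, m * n, n)
  for (k in seq_len(n)) {              # insert n at column position k
    left <- if (k > 1L) p[, seq_len(k - 1L), drop = FALSE] else NULL
    right <- if (k < n) p[, k:(n - 1L), drop = FALSE] else NULL
    out[((k - 1L) * m + 1L):(k * m), ] <- cbind(left, n, right)
  }
  out
}

#' Charge of a postsynaptic current event
#'
#' Area under the baseline-subtracted current over the event window
#' (trapezoid, reported as magnitude, pA*s). The baseline current defaults
#' to the median of the 50 ms immediately preceding the event.
#'
#' @param x a current [trace()] (units pA).
#' @param window numeric `(t_start, t_end)`, s.
#' @param baseline_current pA; computed from the pre-event segment when
#'   `NULL`.
#' @param polarity optional `"EPSC"`/`"IPSC"`; checked against the holding
#'   potential in the trace label (EPSC at -70 mV, IPSC at 0 mV) with a
#'   warning on mismatch.
#' @return one-row data frame `t_start,t_end,area,polarity,
#'   baseline_current`.
#' @export
psc_area <- function(x, window, baseline_current = NULL, polarity = NA) {
  stopifnot(inherits(x, "trace"), length(window) == 2L)
  extent <- c(x$t0, x$t0 + trace_duration(x))
  if (window[1] < extent[1] - 1e-9 || window[2] > extent[2] + 1e-9)
    stop("event window outside the trace", call. = FALSE)
  if (is.null(baseline_current)) {
    b0 <- max(extent[1], window[1] - 0.050)
    baseline_current <- if (window[1] - b0 > 2 / x$fs)
      stats::median(trace_window(x, b0, window[1])$samples) else 0
  }
  if (!is.na(polarity) && grepl("holding", x$label)) {
    hold <- as.numeric(sub(".*holding (-?[0-9.]+) mV.*", "\\1", x$label))
    want <- if (polarity == "EPSC") -70 else 0
    if (is.finite(hold) && hold != want)
      warning(sprintf("%s events are expected at %g mV but trace was held at %g mV",
                      polarity, want, hold), call. = FALSE)
  }
  seg <- trace_window(x, window[1], window[2])
  data.frame(
    t_start = window[1], t_end = window[2],
    area = abs(trapz(trace_times(seg), seg$samples - baseline_current)),
    polarity = as.character(polarity), baseline_current = baseline_current
  )
}

#' EPSC-to-IPSC charge ratio per window
#'
#' Ratio of mean EPSC area to mean IPSC area within the pre and post
#' windows — the net-excitability index — and the post/pre ratio change.
#' Cross-session inference on the ratios is done with [paired_compare()].
#'
#' @param epsc,ipsc data frames with `t_start` and `area` columns (e.g.
#'   rows of [psc_area()] output).
#' @param pre_window,post_window numeric `(t_start, t_end)` each.
#' @return list `ratio_pre`, `ratio_post`, `ratio_change` (post/pre),
#'   `n_epsc`, `n_ipsc` (per-window counts).
#' @export
epsc_ipsc_ratio <- function(epsc, ipsc, pre_window, post_window) {
  mean_in <- function(ev, w) {
    a <- ev$area[ev$t_start >= w[1] & ev$t_start < w[2]]
    if (!length(a)) stop("a window has no events of one polarity",
                         call. = FALSE)
    c(mean = mean(a), n = length(a))
  }
  e_pre <- mean_in(epsc, pre_window); e_post <- mean_in(epsc, post_window)
  i_pre <- mean_in(ipsc, pre_window); i_post <- mean_in(ipsc, post_window)
  if (i_pre["mean"] == 0 || i_post["mean"] == 0)
    stop("zero mean IPSC area: ratio undefined", call. = FALSE)
  r_pre <- unname(e_pre["mean"] / i_pre["mean"])
  r_post <- unname(e_post["mean"] / i_post["mean"])
  list(ratio_pre = r_pre, ratio_post = r_post,
       ratio_change = r_post / r_pre,
       n_epsc = unname(c(pre = e_pre["n"], post = e_post["n"])),
       n_ipsc = unname(c(pre = i_pre["n"], post = i_post["n"])))
}
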