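#' Read a trace from disk
#'
#' Two formats are supported. `"delimited"` is a CSV whose first line is a
#' comment header `# fs=<Hz> units=<mV|pA> t0=<s>` followed by `time,value`
#' columns; it is convenient for small fixtures. `"container"` is a
#' single-file binary store (RDS) with named fields `samples`, `fs`, `t0`,
#' `units`, `label`; round-trips are bit-exact and it is the format of choice
#' for traces at 10-20 kHz.
#'
#' @param path file path.
#' @param format `"delimited"` or `"container"`.
#' @return a [trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, format = c("delimited", "container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "container") {
    obj <- readRDS(path)
    if (!is.list(obj) || !all(c("samples", "fs", "units") %in% names(obj)))
      stop("invalid container: missing samples/fs/units fields", call. = FALSE)
    return(trace(obj$samples, obj$fs, t0 = obj$t0 %||% 0,
                 units = obj$units, label = obj$label %||% ""))
  }
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("delimited trace is missing its '# fs=... units=...' header line",
         call. = FALSE)
  fs <- header_field(header, "fs")
  units <- header_field(header, "units", numeric = FALSE)
  t0 <- tryCatch(header_field(header, "t0"), error = function(e) 0)
  if (is.na(fs) || is.null(units))
    stop("header must declare fs and units", call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "value") %in% names(tab)))
    stop("delimited trace needs 'time' and 'value' columns", call. = FALSE)
  bad <- which(!is.finite(tab$value))
  if (length(bad))
    stop(sprintf("non-finite sample at row %d", bad[1L]), call. = FALSE)
  trace(tab$value, fs = fs, t0 = t0, units = units)
}

header_field <- function(header, key, numeric = TRUE) {
  m <- regmatches(header, regexpr(paste0(key, "=[^[:space:]]+"), header))
  if (!length(m)) {
    if (numeric) stop("missing header field ", key, call. = FALSE) else return(NULL)
  }
  val <- sub(paste0(key, "="), "", m)
  if (numeric) as.numeric(val) else val
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trace to disk
#'
#' @inheritParams read_trace
#' @param x a [trace()].
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, format = c("delimited", "container")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "trace"))
  if (format == "container") {
    saveRDS(unclass(x), path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g units=%s t0=%.10g", x$fs, x$units, x$t0), con)
  utils::write.csv(data.frame(time = trace_times(x), value = x$samples),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

swr_event_cols <- c("t_start", "t_end", "area", "sw_amplitude", "duration_ms",
                    "ripple_count", "ripple_freq", "max_abs_coeff",
                    "accepted", "rejection_reason")

#' Write a table of detected SWR events to CSV
#'
#' One row per event, columns `t_start,t_end,area,sw_amplitude,duration_ms,
#' ripple_count,ripple_freq,max_abs_coeff,accepted,rejection_reason`.
#' Events must already be sorted by `t_start`.
#'
#' @param events a data frame as returned by [detect_swr()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as.data.frame(events)
  missing_cols <- setdiff(swr_event_cols, names(events))
  if (length(missing_cols))
    stop("events table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(events) > 1L && is.unsorted(events$t_start))
    stop("events must be sorted by t_start", call. = FALSE)
  utils::write.csv(events[, swr_event_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an SWR event table written by [write_events()]
#' @param path CSV path.
#' @return a data frame with the standard event columns.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  missing_cols <- setdiff(swr_event_cols, names(tab))
  if (length(missing_cols))
    stop("not an event table; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$accepted <- as.logical(tab$accepted)
  tab$rejection_reason <- as.character(tab$rejection_reason)
  tab
}
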