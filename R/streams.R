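#' Timestamped sensor stream
#'
#' The basic container for one metric from one device: epoch-nanosecond
#' timestamps, sample values, and per-sample validity. Timestamps are stored
#' as doubles holding exact integers (nanosecond ticks are exact below 2^53,
#' i.e. for sessions anchored near a small epoch origin or ~104 days of
#' nanoseconds).
#'
#' @param timestamps_ns numeric vector of strictly increasing integer-valued
#'   epoch-nanosecond timestamps.
#' @param values numeric vector, same length as `timestamps_ns`.
#' @param device_id,metric,units character labels.
#' @param native_rate_hz nominal native sampling rate in Hz.
#' @param valid logical vector of per-sample validity (default all `TRUE`).
#'   Invalid samples are skipped by sample-and-hold fusion.
#' @return An object of class `ts_stream`.
#' @export
ts_stream <- function(timestamps_ns, values, device_id = "device",
                      metric = "metric", units = "", native_rate_hz = NA_real_,
                      valid = NULL) {
  timestamps_ns <- as.numeric(timestamps_ns)
  values <- as.numeric(values)
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  x <- structure(
    list(device_id = device_id, metric = metric, units = units,
         native_rate_hz = native_rate_hz,
         timestamps_ns = timestamps_ns, values = values, valid = valid),
    class = "ts_stream")
  validate_ts_stream(x)
  x
}

#' Validate a ts_stream
#'
#' Checks the structural invariants: equal lengths, strictly increasing
#' integer-valued timestamps, finite values on valid samples.
#'
#' @param x a `ts_stream`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_ts_stream <- function(x) {
  stopifnot(inherits(x, "ts_stream"))
  n <- length(x$timestamps_ns)
  if (length(x$values) != n || length(x$valid) != n)
    stop("ts_stream: timestamps, values and valid must have equal length")
  if (n > 1 && any(diff(x$timestamps_ns) <= 0))
    stop("ts_stream: timestamps must be strictly increasing")
  if (n > 0 && any(x$timestamps_ns != round(x$timestamps_ns)))
    stop("ts_stream: timestamps must be integer nanoseconds")
  if (any(!is.finite(x$values[x$valid])))
    stop("ts_stream: valid samples must be finite")
  invisible(x)
}

#' @export
print.ts_stream <- function(x, ...) {
  n <- length(x$timestamps_ns)
  dur <- if (n > 1) (x$timestamps_ns[n] - x$timestamps_ns[1]) / 1e9 else 0
  cat(sprintf("<ts_stream> %s/%s [%s]: %d samples, %.2f s, nominal %.3g Hz\n",
              x$device_id, x$metric, x$units, n, dur, x$native_rate_hz))
  invisible(x)
}

#' Number of samples in a stream
#' @param x a `ts_stream`.
#' @export
stream_length <- function(x) length(x$timestamps_ns)

#' Read a stream from CSV
#'
#' Expects columns `timestamp_ns,value` and optionally `valid` (0/1 or
#' logical), as written by [write_stream_csv()].
#'
#' @param path file path.
#' @param device_id,metric,units,native_rate_hz metadata labels (not stored
#'   in the CSV).
#' @return a `ts_stream`.
#' @export
read_stream_csv <- function(path, device_id = "device", metric = "metric",
                            units = "", native_rate_hz = NA_real_) {
  if (!file.exists(path)) stop("stream CSV not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("timestamp_ns", "value") %in% names(df)))
    stop("stream CSV must have columns timestamp_ns,value: ", path)
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else NULL
  ts_stream(df$timestamp_ns, df$value, device_id = device_id, metric = metric,
            units = units, native_rate_hz = native_rate_hz, valid = valid)
}

#' Write a stream to CSV
#' @param x a `ts_stream`.
#' @param path output path.
#' @export
write_stream_csv <- function(x, path) {
  validate_ts_stream(x)
  df <- data.frame(timestamp_ns = sprintf("%.0f", x$timestamps_ns),
                   value = format(x$values, digits = 17, trim = TRUE,
                                  scientific = FALSE),
                   valid = as.integer(x$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# interpolate a stream linearly onto arbitrary times (seconds); NA outside
# support. Internal helper used by alignment and agreement.
stream_approx <- function(x, t_s) {
  ts <- x$timestamps_ns[x$valid] / 1e9
  v <- x$values[x$valid]
  if (length(ts) < 2) stop("stream too short to interpolate")
  stats::approx(ts, v, xout = t_s, method = "linear", rule = 1)$y
}
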