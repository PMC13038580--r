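#' Master-clock synchronization configuration
#'
#' @param master_rate_hz master tick rate in Hz (default 200, the highest
#'   native rate among the integrated devices).
#' @param t_start_ns,t_end_ns session bounds in epoch ns; if `NA`, taken
#'   from the union of the input streams (inclusive of the last sample). An
#'   explicit `t_end_ns` is exclusive: ticks cover `[t_start, t_end)`.
#' @param hold_before_first policy for ticks before a stream's first sample:
#'   `"missing"` (default; sentinel `NA` + missing flag) or `"backfill"`
#'   (hold the first sample backwards).
#' @return class `sync_config`.
#' @export
sync_config <- function(master_rate_hz = 200, t_start_ns = NA, t_end_ns = NA,
                        hold_before_first = c("missing", "backfill")) {
  if (master_rate_hz <= 0) stop("master_rate_hz must be > 0")
  structure(list(master_rate_hz = master_rate_hz, t_start_ns = t_start_ns,
                 t_end_ns = t_end_ns,
                 hold_before_first = match.arg(hold_before_first)),
            class = "sync_config")
}

#' Fuse heterogeneous-rate streams onto one master clock
#'
#' Sample-and-hold placeholder up-sampling: for each master tick `t` and
#' each stream, the cell holds the value of the latest valid sample with
#' timestamp `<= t` (a sample timestamped exactly at a tick belongs to that
#' tick). The cell is flagged `"fresh"` if that sample falls in
#' `(previous tick, t]`, `"held"` if it is a repeated placeholder, and
#' `"missing"` before the stream's first sample (under the default policy).
#' No interpolation ever invents values; invalid samples are skipped.
#'
#' Tick spacing is exactly `round(1e9 / master_rate_hz)` ns, so the grid
#' cannot drift over the session. Cell lookup is done by timestamp
#' comparison, never index arithmetic, so device jitter and non-integer rate
#' ratios are handled exactly.
#'
#' @param streams list of `ts_stream`s.
#' @param cfg a [sync_config()].
#' @param events optional `event_timeline` carried through to the table.
#' @return class `session_table`: list with `tick_times_ns`, `columns`
#'   (named list of numeric vectors, names `device.metric`), `freshness`
#'   (named list of character vectors: `"fresh"`/`"held"`/`"missing"`),
#'   `master_rate_hz`, `events`, `stream_meta`.
#' @export
synchronize <- function(streams, cfg = sync_config(), events = NULL) {
  if (length(streams) < 1) stop("need at least one stream")
  lapply(streams, validate_ts_stream)
  rates <- vapply(streams, function(s) s$native_rate_hz, numeric(1))
  if (any(!is.na(rates) & rates > cfg$master_rate_hz))
    warning("master rate below a stream's native rate; samples will be dropped")
  nonempty <- Filter(function(s) sum(s$valid) > 0, streams)
  if (!length(nonempty)) stop("all streams empty")
  t0 <- if (is.na(cfg$t_start_ns))
    min(vapply(nonempty, function(s) min(s$timestamps_ns[s$valid]), numeric(1)))
  else cfg$t_start_ns
  t1 <- if (is.na(cfg$t_end_ns))
    max(vapply(nonempty, function(s) max(s$timestamps_ns[s$valid]), numeric(1)))
  else cfg$t_end_ns
  dt <- round(1e9 / cfg$master_rate_hz)
  # an explicit end bound is exclusive ([t0, t1)); an end derived from the
  # data is inclusive — the grid is extended to the tick at or after the
  # last sample so that no sample is left unrepresented
  n_ticks <- if (is.na(cfg$t_end_ns)) ceiling((t1 - t0) / dt) + 1
  else floor((t1 - t0) / dt) + 1
  ticks <- t0 + (seq_len(n_ticks) - 1) * dt
  if (!is.na(cfg$t_end_ns)) {
    ticks <- ticks[ticks < t1]
    n_ticks <- length(ticks)
  }

  columns <- list()
  freshness <- list()
  meta <- list()
  for (s in streams) {
    key <- paste(s$device_id, s$metric, sep = ".")
    ts <- s$timestamps_ns[s$valid]
    v <- s$values[s$valid]
    col <- rep(NA_real_, n_ticks)
    fl <- rep("missing", n_ticks)
    if (length(ts) == 0) {
      warning("stream ", key, " has no valid samples; column all missing")
    } else {
      # index of latest sample with timestamp <= tick (0 if none)
      idx <- findInterval(ticks, ts)
      has <- idx >= 1
      col[has] <- v[idx[has]]
      # fresh iff the used sample lies in (tick - dt, tick]
      fl[has] <- ifelse(ts[idx[has]] > ticks[has] - dt, "fresh", "held")
      if (cfg$hold_before_first == "backfill" && any(!has)) {
        col[!has] <- v[1]
        fl[!has] <- "held"
      }
    }
    columns[[key]] <- col
    freshness[[key]] <- fl
    meta[[key]] <- list(device_id = s$device_id, metric = s$metric,
                        units = s$units, native_rate_hz = s$native_rate_hz)
  }
  structure(list(tick_times_ns = ticks, columns = columns,
                 freshness = freshness, master_rate_hz = cfg$master_rate_hz,
                 events = events, stream_meta = meta),
            class = "session_table")
}

#' @export
print.session_table <- function(x, ...) {
  cat(sprintf("<session_table> %d ticks @ %g Hz, %d columns\n",
              length(x$tick_times_ns), x$master_rate_hz, length(x$columns)))
  for (key in names(x$columns)) {
    fl <- x$freshness[[key]]
    cat(sprintf("  %-24s fresh %6d  held %6d  missing %6d\n", key,
                sum(fl == "fresh"), sum(fl == "held"), sum(fl == "missing")))
  }
  invisible(x)
}

#' Recover a native-rate stream from a synchronized column
#'
#' Inverse of the placeholder expansion: returns only the fresh cells of one
#' column, at their tick times — the native-rate stream up to tick
#' quantization.
#'
#' @param table a `session_table`.
#' @param stream_id column key (`"device.metric"`).
#' @return a `ts_stream`.
#' @export
deduplicate_held <- function(table, stream_id) {
  stopifnot(inherits(table, "session_table"))
  if (!stream_id %in% names(table$columns))
    stop("no such column: ", stream_id)
  fresh <- table$freshness[[stream_id]] == "fresh"
  m <- table$stream_meta[[stream_id]]
  ts_stream(table$tick_times_ns[fresh], table$columns[[stream_id]][fresh],
            device_id = m$device_id, metric = m$metric, units = m$units,
            native_rate_hz = m$native_rate_hz)
}

#' Persist a session table (lossless round trip)
#'
#' Writes the full table — tick grid, value columns, per-cell freshness
#' flags, stream metadata, and the event log — as a structured JSON session
#' file at full double precision. [read_session()] restores an identical
#' object. Freshness flags are stored as compact integer codes
#' (0 missing / 1 fresh / 2 held).
#'
#' @param table a `session_table`.
#' @param path output path (conventionally `.session.json`).
#' @export
write_session <- function(table, path) {
  stopifnot(inherits(table, "session_table"))
  code <- c(missing = 0L, fresh = 1L, held = 2L)
  payload <- list(
    format = "physiofuse-session", version = 1L,
    master_rate_hz = table$master_rate_hz,
    tick_start_ns = table$tick_times_ns[1],
    tick_dt_ns = round(1e9 / table$master_rate_hz),
    n_ticks = length(table$tick_times_ns),
    columns = table$columns,
    freshness = lapply(table$freshness, function(f) unname(code[f])),
    stream_meta = table$stream_meta,
    events = if (is.null(table$events)) NULL else as.data.frame(table$events))
  # digits = I(17): 17 significant digits round-trips doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_session
#' @return `read_session()` returns the restored `session_table`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path)
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("corrupt session file ", path, ": ",
                                         conditionMessage(e)))
  if (is.null(p$format) || p$format != "physiofuse-session")
    stop("not a physiofuse session file: ", path)
  ticks <- p$tick_start_ns + (seq_len(p$n_ticks) - 1) * p$tick_dt_ns
  decode <- c("missing", "fresh", "held")
  events <- if (is.null(p$events) || (is.data.frame(p$events) && !nrow(p$events)))
    NULL
  else structure(p$events, class = c("event_timeline", "data.frame"))
  structure(list(
    tick_times_ns = ticks,
    columns = lapply(p$columns, as.numeric),
    freshness = lapply(p$freshness, function(f) decode[f + 1L]),
    master_rate_hz = p$master_rate_hz,
    events = events,
    stream_meta = lapply(p$stream_meta, function(m)
      list(device_id = m$device_id, metric = m$metric, units = m$units,
           native_rate_hz = as.numeric(m$native_rate_hz)))),
    class = "session_table")
}
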