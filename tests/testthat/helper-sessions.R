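# shared fixtures, all generated in code

# a random stream with jittered sampling at roughly rate_hz over [0, dur_s)
random_stream <- function(rate_hz, dur_s, id = "dev", metric = "m",
                          jitter = 0.1) {
  n <- max(2L, floor(dur_s * rate_hz))
  ts <- (seq_len(n) - 1) / rate_hz
  if (jitter > 0)
    ts <- ts + stats::runif(n, 0, jitter / rate_hz)
  ts <- sort(ts)
  ts_stream(round(ts * 1e9), stats::rnorm(n), device_id = id,
            metric = metric, native_rate_hz = rate_hz)
}

# brute-force sample-and-hold oracle: per-tick linear scan for the latest
# valid sample; intentionally naive and independent of synchronize()
brute_force_sync <- function(streams, master_rate_hz, t_start_ns, t_end_ns) {
  dt <- round(1e9 / master_rate_hz)
  ticks <- seq(t_start_ns, t_end_ns - 1, by = dt)
  out <- list()
  for (s in streams) {
    key <- paste(s$device_id, s$metric, sep = ".")
    col <- rep(NA_real_, length(ticks))
    fl <- rep("missing", length(ticks))
    for (j in seq_along(ticks)) {
      best <- NA_integer_
      for (i in seq_along(s$timestamps_ns)) {
        if (s$valid[i] && s$timestamps_ns[i] <= ticks[j]) best <- i
      }
      if (!is.na(best)) {
        col[j] <- s$values[best]
        fl[j] <- if (s$timestamps_ns[best] > ticks[j] - dt) "fresh" else "held"
      }
    }
    out[[key]] <- list(values = col, freshness = fl)
  }
  list(ticks = ticks, cols = out)
}

# single-phase timeline of the given duration
flat_timeline <- function(dur_s = 60, label = "phase") {
  make_timeline(protocol_template(phases = data.frame(
    label = label, duration_s = dur_s, pressure_mmhg = NA_real_,
    zone_lo = NA_real_, zone_hi = NA_real_)))
}

match_events <- physiofuse:::match_events
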