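#' Device error model for simulated wearables
#'
#' Captures how a device degrades the metric it reports: reporting rate,
#' constant bias, response lag, sample jitter, random dropout, and a clock
#' offset between its onboard clock and the reference clock.
#'
#' @param reporting_rate_hz reporting rate in Hz (> 0).
#' @param bias_bpm constant additive bias, in the metric's units.
#' @param response_lag_s device response lag in seconds (device reports the
#'   physiology from `lag` seconds ago).
#' @param jitter_sd standard deviation of white reporting noise.
#' @param dropout_prob per-sample probability that a report is lost.
#' @param clock_offset_s offset of the device clock relative to the
#'   reference clock, in seconds (used for cached copies).
#' @return an object of class `device_error_model`.
#' @export
device_error_model <- function(reporting_rate_hz = 1, bias_bpm = 0,
                               response_lag_s = 0, jitter_sd = 0,
                               dropout_prob = 0, clock_offset_s = 0) {
  if (reporting_rate_hz <= 0) stop("reporting_rate_hz must be > 0")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0,1]")
  structure(list(reporting_rate_hz = reporting_rate_hz, bias_bpm = bias_bpm,
                 response_lag_s = response_lag_s, jitter_sd = jitter_sd,
                 dropout_prob = dropout_prob, clock_offset_s = clock_offset_s),
            class = "device_error_model")
}

#' Simulate a protocol-driven heart-rate trajectory
#'
#' Within each protocol phase the heart rate relaxes exponentially (first
#' order, time constant `tau_s`) toward the phase target: the midpoint of
#' the phase's HRmax zone for exercise phases, or `hr_rest` for rest and
#' recovery phases. The trajectory is continuous at phase boundaries and is
#' evaluated in closed form on a regular grid.
#'
#' @param timeline an `event_timeline` from [make_timeline()] (exercise
#'   phases need `zone_lo`/`zone_hi` columns).
#' @param hr_rest,hr_max resting and maximum heart rate in bpm.
#' @param tau_s first-order time constant in seconds (default 30 s);
#'   `tau_s = 0` snaps instantly to the target.
#' @param grid_hz evaluation grid rate (default 10 Hz).
#' @return class `hr_trajectory`: list with `times_s` (relative to timeline
#'   start), `hr_bpm`, `start_ns`, `timeline`.
#' @export
simulate_hr_trajectory <- function(timeline, hr_rest = 60, hr_max = 190,
                                   tau_s = 30, grid_hz = 10) {
  if (hr_rest >= hr_max) stop("hr_rest must be < hr_max")
  start_ns <- min(timeline$start_ns)
  dur <- timeline_duration_s(timeline)
  times <- seq(0, dur, by = 1 / grid_hz)
  hr <- numeric(length(times))
  hr_cur <- hr_rest
  for (i in seq_len(nrow(timeline))) {
    t0 <- (timeline$start_ns[i] - start_ns) / 1e9
    t1 <- (timeline$end_ns[i] - start_ns) / 1e9
    zl <- timeline$zone_lo[i]
    target <- if (!is.null(zl) && !is.na(zl))
      hr_max * (timeline$zone_lo[i] + timeline$zone_hi[i]) / 2 else hr_rest
    idx <- which(times >= t0 & (times < t1 | i == nrow(timeline)))
    if (tau_s <= 0) {
      hr[idx] <- target
      hr_cur <- target
    } else {
      hr[idx] <- target + (hr_cur - target) * exp(-(times[idx] - t0) / tau_s)
      hr_cur <- target + (hr_cur - target) * exp(-(t1 - t0) / tau_s)
    }
  }
  hr <- pmin(pmax(hr, 30), 220)
  structure(list(times_s = times, hr_bpm = hr, start_ns = start_ns,
                 timeline = timeline), class = "hr_trajectory")
}

#' Evaluate an hr_trajectory at arbitrary times
#' @param traj an `hr_trajectory`.
#' @param t_s times in seconds relative to the trajectory start.
#' @return heart rate in bpm (constant-extrapolated outside the grid).
#' @export
hr_at <- function(traj, t_s) {
  stats::approx(traj$times_s, traj$hr_bpm, xout = t_s, rule = 2)$y
}

# place beats by integrating instantaneous rate: a beat fires each time the
# accumulated phase crosses an integer, so HR(t) is exactly recoverable from
# the inter-beat intervals.
beat_times_from_trajectory <- function(traj, dt = 0.005) {
  t <- seq(0, max(traj$times_s), by = dt)
  rate <- hr_at(traj, t) / 60                  # beats per second
  phase <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  n_beats <- floor(phase[length(phase)])
  if (n_beats < 1) return(numeric(0))
  stats::approx(phase, t, xout = seq_len(n_beats))$y
}

# stylized PQRST template evaluated at offsets (s) from the R peak, in mV
ecg_template <- function(dt_s, r_amp = 1) {
  g <- function(mu, sd) exp(-0.5 * ((dt_s - mu) / sd)^2)
  r_amp * g(0, 0.012) - 0.15 * g(-0.035, 0.010) - 0.20 * g(0.035, 0.012) +
    0.12 * g(-0.200, 0.040) + 0.30 * g(0.250, 0.050)
}

#' Synthesize an ECG stream from a heart-rate trajectory
#'
#' Beats are placed by integrating the instantaneous rate (time-warping), so
#' the trajectory is exactly recoverable from the inter-beat intervals. Each
#' beat contributes a stylized Gaussian-bump PQRST template (R amplitude
#' 1 mV). Motion segments add broadband noise plus low-frequency baseline
#' wander scaled by a per-segment degradation factor.
#'
#' @param traj an `hr_trajectory`.
#' @param fs_hz sampling rate (default 200 Hz); must exceed twice the
#'   maximum heart frequency.
#' @param noise_sd baseline white-noise SD in mV (default 0).
#' @param motion_segments optional data.frame with `start_s`, `end_s`,
#'   `factor`; within each segment broadband noise of SD
#'   `0.02 * factor` mV and baseline wander of amplitude `0.05 * factor` mV
#'   are added.
#' @param seed RNG seed.
#' @param start_ns epoch-ns timestamp of the first sample.
#' @return list with `stream` (a `ts_stream`, mV) and `beat_times_s`
#'   (ground-truth R-peak times, seconds relative to `start_ns`).
#' @export
synth_ecg <- function(traj, fs_hz = 200, noise_sd = 0, motion_segments = NULL,
                      seed = 1, start_ns = traj$start_ns) {
  if (fs_hz <= 2 * max(traj$hr_bpm) / 60)
    stop("fs_hz must exceed twice the maximum heart frequency")
  set.seed(seed)
  beats <- beat_times_from_trajectory(traj)
  dur <- max(traj$times_s)
  t <- seq(0, dur, by = 1 / fs_hz)
  x <- numeric(length(t))
  half <- 0.45                                   # template support (s)
  for (b in beats) {
    i0 <- max(1L, ceiling((b - half) * fs_hz) + 1L)
    i1 <- min(length(t), floor((b + half) * fs_hz) + 1L)
    if (i1 >= i0) x[i0:i1] <- x[i0:i1] + ecg_template(t[i0:i1] - b)
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  if (!is.null(motion_segments)) {
    for (k in seq_len(nrow(motion_segments))) {
      idx <- which(t >= motion_segments$start_s[k] & t < motion_segments$end_s[k])
      if (!length(idx)) next
      f <- motion_segments$factor[k]
      wander <- 0.05 * f * sin(2 * pi * 0.3 * t[idx] + stats::runif(1, 0, 2 * pi)) +
        0.03 * f * sin(2 * pi * 0.7 * t[idx] + stats::runif(1, 0, 2 * pi))
      x[idx] <- x[idx] + stats::rnorm(length(idx), 0, 0.02 * f) + wander
    }
  }
  stream <- ts_stream(round(start_ns + t * 1e9), x, device_id = "sim_ecg",
                      metric = "ecg", units = "mV", native_rate_hz = fs_hz)
  list(stream = stream, beat_times_s = beats)
}

#' Simulate a device-reported heart-rate stream
#'
#' Samples the ground-truth trajectory at the device reporting rate, applies
#' the device error model (response lag, additive bias, white jitter), and
#' drops samples at the dropout probability.
#'
#' @param traj an `hr_trajectory`.
#' @param model a [device_error_model()].
#' @param seed RNG seed.
#' @param start_ns epoch-ns timestamp of the session start.
#' @return a `ts_stream` of reported HR (bpm).
#' @export
synth_device_hr <- function(traj, model, seed = 1, start_ns = traj$start_ns) {
  stopifnot(inherits(model, "device_error_model"))
  set.seed(seed)
  dur <- max(traj$times_s)
  t <- seq(0, dur, by = 1 / model$reporting_rate_hz)
  v <- hr_at(traj, t - model$response_lag_s) + model$bias_bpm
  if (model$jitter_sd > 0) v <- v + stats::rnorm(length(v), 0, model$jitter_sd)
  keep <- stats::runif(length(t)) >= model$dropout_prob
  ts_stream(round(start_ns + t[keep] * 1e9), v[keep], device_id = "sim_hr",
            metric = "hr", units = "bpm",
            native_rate_hz = model$reporting_rate_hz)
}

#' Simulate a tissue-oxygenation (StO2) trace over an occlusion protocol
#'
#' Baseline plateau; during each cuff phase the saturation falls linearly,
#' with slope `desat_rate` (percent per minute per mmHg) times the cuff
#' pressure — so desaturation is proportional to pressure; during recovery
#' it relaxes
#' exponentially back to baseline with a transient reperfusion overshoot
#' (alpha-function, peaking at `overshoot_peak_s`). Values are clipped to
#' [0, 100].
#'
#' @param timeline occlusion `event_timeline` (needs `pressure_mmhg`).
#' @param kinetics list: `desat_rate` (%/min per mmHg, default 0.1),
#'   `overshoot_pct` (default 5), `tau_s` (recovery time constant, default
#'   30), `overshoot_peak_s` (default 30), `baseline_pct` (default 70).
#' @param rate_hz sampling rate (default 0.5 Hz, the muscle-oximeter rate).
#' @param noise_sd white measurement noise SD in percent (default 0).
#' @param seed RNG seed.
#' @return a `ts_stream` of StO2 in percent.
#' @export
synth_sto2_occlusion <- function(timeline,
                                 kinetics = list(), rate_hz = 0.5,
                                 noise_sd = 0, seed = 1) {
  k <- utils::modifyList(list(desat_rate = 0.1, overshoot_pct = 5,
                              tau_s = 30, overshoot_peak_s = 30,
                              baseline_pct = 70), kinetics)
  set.seed(seed)
  start_ns <- min(timeline$start_ns)
  dur <- timeline_duration_s(timeline)
  t <- seq(0, dur, by = 1 / rate_hz)
  v <- numeric(length(t))
  cur <- k$baseline_pct
  for (i in seq_len(nrow(timeline))) {
    t0 <- (timeline$start_ns[i] - start_ns) / 1e9
    t1 <- (timeline$end_ns[i] - start_ns) / 1e9
    idx <- which(t >= t0 & (t < t1 | i == nrow(timeline)))
    p <- timeline$pressure_mmhg[i]
    if (!is.na(p) && p > 0) {                       # occlusion: linear desat
      slope <- -k$desat_rate * p / 60               # %/s
      v[idx] <- cur + slope * (t[idx] - t0)
      cur <- cur + slope * (t1 - t0)
    } else if (i > 1) {                             # recovery with overshoot
      # reperfusion hyperemia only follows an actual oxygen deficit
      ov <- if (cur < k$baseline_pct) k$overshoot_pct else 0
      rel <- t[idx] - t0
      v[idx] <- k$baseline_pct + (cur - k$baseline_pct) * exp(-rel / k$tau_s) +
        ov * (rel / k$overshoot_peak_s) * exp(1 - rel / k$overshoot_peak_s)
      rel1 <- t1 - t0
      cur <- k$baseline_pct + (cur - k$baseline_pct) * exp(-rel1 / k$tau_s) +
        ov * (rel1 / k$overshoot_peak_s) * exp(1 - rel1 / k$overshoot_peak_s)
    } else {                                        # pre-occlusion baseline
      v[idx] <- cur
    }
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  v <- pmin(pmax(v, 0), 100)
  ts_stream(round(start_ns + t * 1e9), v, device_id = "sim_sto2",
            metric = "sto2", units = "%", native_rate_hz = rate_hz)
}

#' Split a stream into a streamed copy with dropouts and a cached copy with
#' a clock offset
#'
#' Emulates BLE telemetry loss with onboard caching: the streamed copy loses
#' all samples inside the dropout intervals; the cached copy keeps every
#' sample but carries the device clock, i.e. all timestamps shifted by
#' `clock_offset_s`.
#'
#' @param stream a `ts_stream`.
#' @param dropout_intervals data.frame with `start_s`, `end_s` relative to
#'   the stream's first sample (or NULL for none).
#' @param clock_offset_s device-clock offset in seconds.
#' @return list(`streamed`, `cached`) of `ts_stream`s.
#' @export
split_streamed_cached <- function(stream, dropout_intervals = NULL,
                                  clock_offset_s = 0) {
  validate_ts_stream(stream)
  t0 <- stream$timestamps_ns[1]
  rel <- (stream$timestamps_ns - t0) / 1e9
  keep <- rep(TRUE, length(rel))
  if (!is.null(dropout_intervals)) {
    for (i in seq_len(nrow(dropout_intervals)))
      keep <- keep & !(rel >= dropout_intervals$start_s[i] &
                         rel < dropout_intervals$end_s[i])
  }
  streamed <- stream
  streamed$timestamps_ns <- stream$timestamps_ns[keep]
  streamed$values <- stream$values[keep]
  streamed$valid <- stream$valid[keep]
  cached <- stream
  cached$device_id <- paste0(stream$device_id, "_cached")
  cached$timestamps_ns <- stream$timestamps_ns + round(clock_offset_s * 1e9)
  list(streamed = streamed, cached = cached)
}
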