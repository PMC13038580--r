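#' Beat series: R-peak times, IBIs, instantaneous HR
#'
#' @param rpeak_times_s strictly increasing R-peak times in seconds.
#' @param rpeak_amplitudes amplitudes read from the raw signal at the
#'   detected peaks (same length).
#' @return class `beat_series`: adds `ibi_s` (successive differences),
#'   `hr_inst_bpm` (`60 / ibi`), and `hr_times_s` (each instantaneous HR is
#'   timestamped at the second beat of its pair).
#' @export
beat_series <- function(rpeak_times_s, rpeak_amplitudes = NULL) {
  if (is.unsorted(rpeak_times_s, strictly = TRUE))
    stop("beat times must be strictly increasing")
  if (is.null(rpeak_amplitudes))
    rpeak_amplitudes <- rep(NA_real_, length(rpeak_times_s))
  ibi <- diff(rpeak_times_s)
  structure(list(rpeak_times_s = rpeak_times_s,
                 rpeak_amplitudes = rpeak_amplitudes,
                 ibi_s = ibi, hr_inst_bpm = 60 / ibi,
                 hr_times_s = rpeak_times_s[-1]),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, mean HR %.1f bpm\n",
              length(x$rpeak_times_s),
              if (length(x$ibi_s)) mean(60 / x$ibi_s) else NA))
  invisible(x)
}

# moving average by cumulative sum, window w samples
moving_mean <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - (w %/% 2))
  hi <- pmin(n, seq_len(n) + ((w + 1L) %/% 2) - 1L)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect R peaks in an ECG stream
#'
#' Pan-Tompkins-style detector: zero-phase band-pass (default 8--20 Hz,
#' Butterworth order 3), differentiation, squaring, moving-window
#' integration (150 ms), an adaptive signal/noise threshold with a 250 ms
#' refractory period, and RR-interval searchback (gaps longer than 1.6x
#' the local median RR are re-searched at a reduced energy level, which
#' prevents threshold-inflation miss cascades at high heart rates). Peak
#' locations are refined on the band-passed signal and amplitudes are read
#' from the raw (unfiltered) signal at the detected indices, so the
#' detector is invariant to amplitude scaling.
#'
#' @param ecg a `ts_stream` of ECG.
#' @param fs_hz sampling rate in Hz (>= 100).
#' @param band band-pass corners in Hz.
#' @param refractory_s minimum separation between detected peaks.
#' @return a [beat_series()] (zero beats, with a warning, on flat input).
#' @export
detect_rpeaks <- function(ecg, fs_hz = 200, band = c(8, 20),
                          refractory_s = 0.25) {
  validate_ts_stream(ecg)
  if (fs_hz < 100) stop("fs_hz must be >= 100 Hz")
  x <- ecg$values[ecg$valid]
  t <- ecg$timestamps_ns[ecg$valid] / 1e9
  if (length(x) < 5 * fs_hz) stop("need at least 5 s of ECG")
  if (stats::sd(x) == 0) {
    warning("flat ECG signal; no beats detected")
    return(beat_series(numeric(0), numeric(0)))
  }
  bp <- signal::filtfilt(signal::butter(3, band / (fs_hz / 2), type = "pass"), x)
  sq <- c(0, diff(bp))^2
  integ <- moving_mean(sq, max(3L, round(0.150 * fs_hz)))
  refr <- round(refractory_s * fs_hz)

  # candidate local maxima of the integrated energy
  n <- length(integ)
  is_max <- c(FALSE, integ[2:(n - 1)] >= integ[1:(n - 2)] &
                integ[2:(n - 1)] > integ[3:n], FALSE)
  cand <- which(is_max)
  cand <- cand[order(integ[cand], decreasing = TRUE)]
  cand <- sort(cand[!duplicated(floor(cand / refr))])  # thin dense maxima

  spki <- stats::quantile(integ, 0.98, names = FALSE)
  npki <- stats::quantile(integ, 0.50, names = FALSE)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] >= thr && (i - last) > refr) {
      peaks <- c(peaks, i)
      last <- i
      spki <- 0.125 * integ[i] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  # searchback: a beat rejected once inflates the noise estimate and can
  # cascade into every-other-beat misses; RR gaps longer than 1.6x the
  # local median RR are re-searched at a reduced (local) energy level
  cand_all <- which(is_max)
  for (pass in 1:5) {
    if (length(peaks) < 5) break
    rr <- diff(peaks)
    loc_rr <- vapply(seq_along(rr), function(i)
      stats::median(rr[max(1, i - 4):min(length(rr), i + 4)]), numeric(1))
    lvl <- 0.3 * moving_mean(integ[peaks], 9)
    added <- integer(0)
    for (g in which(rr > 1.6 * loc_rr)) {
      inside <- cand_all[cand_all > peaks[g] + refr &
                           cand_all < peaks[g + 1] - refr]
      inside <- inside[integ[inside] >= lvl[g]]
      if (length(inside)) added <- c(added, inside[which.max(integ[inside])])
    }
    if (!length(added)) break
    peaks <- sort(c(peaks, added))
  }
  if (!length(peaks)) {
    warning("no beats detected")
    return(beat_series(numeric(0), numeric(0)))
  }
  # refine: strongest band-passed deflection within +/-150 ms of each
  # energy peak, then read the amplitude from the raw signal
  w <- as.integer(round(0.150 * fs_hz))
  loc <- vapply(as.integer(peaks), function(i) {
    lo <- max(1L, i - w); hi <- min(length(bp), i + w)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  w2 <- as.integer(round(0.025 * fs_hz))
  loc <- vapply(loc, function(i) {
    lo <- max(1L, i - w2); hi <- min(length(x), i + w2)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  loc <- sort(unique(loc))
  # enforce the refractory on final locations, keeping larger amplitudes
  keep <- rep(TRUE, length(loc))
  for (i in seq_along(loc)[-1]) {
    j <- max(which(keep[1:(i - 1)]))
    if ((loc[i] - loc[j]) <= refr) {
      if (x[loc[i]] > x[loc[j]]) keep[j] <- FALSE else keep[i] <- FALSE
    }
  }
  loc <- loc[keep]
  beat_series(t[loc], x[loc])
}

#' Smooth instantaneous HR with a centered rolling mean over beats
#'
#' Averages over exactly `window_beats` consecutive instantaneous-HR
#' samples, centered on each beat; at the edges the window shrinks
#' symmetrically down to a single sample. The output is timestamped at the
#' center beat.
#'
#' @param beats a `beat_series`.
#' @param window_beats window length in beats (default 100).
#' @param start_ns epoch-ns origin for the output stream (default 0, i.e.
#'   beat times are already session-relative seconds).
#' @return a `ts_stream` of smoothed HR (bpm).
#' @export
smooth_hr <- function(beats, window_beats = 100, start_ns = 0) {
  stopifnot(inherits(beats, "beat_series"))
  hr <- beats$hr_inst_bpm
  if (!length(hr)) stop("no inter-beat intervals to smooth")
  sm <- moving_mean(hr, window_beats)
  ts_stream(round(start_ns + beats$hr_times_s * 1e9), sm,
            device_id = "ecg_hr", metric = "hr", units = "bpm",
            native_rate_hz = NA_real_)
}

# greedy one-to-one matching of detected to true event times within tol_s
match_events <- function(detected_s, truth_s, tol_s = 0.05) {
  used <- rep(FALSE, length(detected_s))
  hits <- 0L
  for (bt in truth_s) {
    d <- abs(detected_s - bt)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(true_pos = hits, false_pos = sum(!used), matched_mask = used)
}

#' Per-phase R-peak detection quality report
#'
#' For each protocol phase: detection count, mean amplitude and amplitude
#' coefficient of variation, percent of implausible IBIs (outside
#' 0.27--2.0 s, i.e. 30--220 bpm), and percent of ectopic-flagged beats
#' (|change in IBI| exceeding 20% of the local median IBI). With ground
#' truth, adds sensitivity and positive predictive value at a ±50 ms
#' matching tolerance.
#'
#' @param beats a `beat_series` (times in seconds on the timeline clock).
#' @param timeline an `event_timeline`.
#' @param truth_beat_times_s optional ground-truth beat times.
#' @param ibi_bounds_s plausibility bounds on the IBI (default
#'   `c(0.27, 2.0)`).
#' @param tol_s match tolerance for sensitivity/PPV (default 0.05 s).
#' @return class `quality_report`: data.frame, one row per phase.
#' @export
rpeak_quality <- function(beats, timeline, truth_beat_times_s = NULL,
                          ibi_bounds_s = c(0.27, 2.0), tol_s = 0.05) {
  stopifnot(inherits(beats, "beat_series"))
  t0 <- min(timeline$start_ns)
  bt_ns <- t0 + beats$rpeak_times_s * 1e9
  phase <- phase_at(timeline, bt_ns)
  ibi <- beats$ibi_s
  # local median over a 9-beat neighborhood for the ectopic rule
  locmed <- vapply(seq_along(ibi), function(i) {
    lo <- max(1L, i - 4L); hi <- min(length(ibi), i + 4L)
    stats::median(ibi[lo:hi])
  }, numeric(1))
  dibi <- c(NA, abs(diff(ibi)))
  ectopic <- !is.na(dibi) & dibi > 0.2 * locmed
  implaus <- ibi < ibi_bounds_s[1] | ibi > ibi_bounds_s[2]

  rows <- lapply(seq_len(nrow(timeline)), function(i) {
    lab <- timeline$label[i]
    in_ph <- !is.na(phase) & phase == lab
    idx_ibi <- which(in_ph[-1])         # IBI attributed to its second beat
    amp <- beats$rpeak_amplitudes[in_ph]
    out <- data.frame(
      phase = lab,
      detection_count = sum(in_ph),
      expected_count = NA_integer_,
      amplitude_mean = if (length(amp)) mean(amp) else NA_real_,
      amplitude_cv = if (length(amp) > 1 && isTRUE(mean(amp) != 0))
        stats::sd(amp) / abs(mean(amp)) else NA_real_,
      pct_implausible_ibi = if (length(idx_ibi))
        100 * mean(implaus[idx_ibi]) else NA_real_,
      pct_ectopic_flagged = if (length(idx_ibi))
        100 * mean(ectopic[idx_ibi], na.rm = TRUE) else NA_real_,
      sensitivity_pct = NA_real_, ppv_pct = NA_real_)
    if (!is.null(truth_beat_times_s)) {
      tr_ns <- t0 + truth_beat_times_s * 1e9
      tr <- truth_beat_times_s[!is.na(phase_at(timeline, tr_ns)) &
                                 phase_at(timeline, tr_ns) == lab]
      out$expected_count <- length(tr)
      if (length(tr)) {
        m <- match_events(beats$rpeak_times_s[in_ph], tr, tol_s)
        out$sensitivity_pct <- 100 * m$true_pos / length(tr)
        out$ppv_pct <- if (sum(in_ph))
          100 * m$true_pos / sum(in_ph) else NA_real_
      }
    }
    out
  })
  structure(do.call(rbind, rows), class = c("quality_report", "data.frame"))
}
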