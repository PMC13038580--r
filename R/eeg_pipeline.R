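#' Band-pass preprocess an EEG recording
#'
#' Linear detrend per channel, then a zero-phase Butterworth band-pass:
#' an order-4 high-pass at the lower corner cascaded with an order-4
#' low-pass at the upper corner, each applied forward-backward
#' (`filtfilt`). The cascade realizes the 0.1--30 Hz band with good
#' numerical conditioning at the very low high-pass corner.
#'
#' @param rec an `eeg_recording`.
#' @param band band corners in Hz (default `c(0.1, 30)`).
#' @return the filtered `eeg_recording`.
#' @export
eeg_preprocess <- function(rec, band = c(0.1, 30)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  hp <- signal::butter(4, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(4, band[2] / (fs / 2), type = "low")
  n <- ncol(rec$data)
  tt <- seq_len(n)
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ]
    fit <- stats::lm.fit(cbind(1, tt), x)
    x <- x - fit$fitted.values
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    rec$data[ch, ] <- x
  }
  rec
}

# zero-phase low-pass helper
lowpass <- function(x, fs, corner = 4, order = 4) {
  signal::filtfilt(signal::butter(order, corner / (fs / 2), type = "low"), x)
}

#' Detect blinks on the frontal channel
#'
#' Low-passes the frontal channel (default Fz, <= 4 Hz), then marks peaks
#' exceeding an adaptive threshold `median + k * MAD` (default k = 4) with a
#' minimum separation of 500 ms. The adaptive threshold makes detection
#' invariant to overall amplitude scaling.
#'
#' @param rec an `eeg_recording`.
#' @param channel channel label to use (default `"Fz"`).
#' @param k MAD multiplier (default 4).
#' @param min_sep_s minimum separation between blinks (default 0.5 s).
#' @return integer sample indices of blink peaks.
#' @export
detect_blinks <- function(rec, channel = "Fz", k = 4, min_sep_s = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  ci <- match(channel, rec$channel_labels)
  if (is.na(ci)) stop("no such channel: ", channel)
  x <- lowpass(rec$data[ci, ], rec$fs_hz)
  thr <- stats::median(x) + k * stats::mad(x)
  n <- length(x)
  is_pk <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
             FALSE) & x > thr
  pk <- which(is_pk)
  if (!length(pk)) return(integer(0))
  # keep the largest peak within each min_sep_s neighborhood
  pk <- pk[order(x[pk], decreasing = TRUE)]
  sep <- round(min_sep_s * rec$fs_hz)
  kept <- integer(0)
  for (i in pk) if (!length(kept) || all(abs(kept - i) > sep))
    kept <- c(kept, i)
  sort(kept)
}

# deflation FastICA (tanh contrast) on channels x samples; returns the
# unmixing matrix applied to centered data plus per-unit convergence flags.
# Units are extracted one at a time with Gram-Schmidt deflation, so the
# strongly non-Gaussian sources (blinks) converge first; later units
# spanning the near-Gaussian background may not converge, which is harmless
# for component removal (any orthonormal completion of the basis yields the
# same cleaned signal).
fastica_unmix <- function(X, max_iter = 300, tol = 1e-5, seed = 1) {
  ctr <- rowMeans(X)
  Xc <- X - ctr
  C <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-9
  K <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*% t(eg$vectors[, keep])
  Z <- K %*% Xc
  p <- nrow(Z)
  set.seed(seed)
  W <- matrix(0, p, p)
  converged <- logical(p)
  for (comp in seq_len(p)) {
    w <- stats::rnorm(p)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wz <- drop(w %*% Z)
      g <- tanh(wz)
      w1 <- Z %*% g / ncol(Z) - mean(1 - g^2) * w
      if (comp > 1) {
        prev <- W[seq_len(comp - 1), , drop = FALSE]
        w1 <- w1 - t(prev) %*% (prev %*% w1)
      }
      nrm <- sqrt(sum(w1^2))
      if (nrm < 1e-12) break
      w1 <- drop(w1) / nrm
      done <- abs(abs(sum(w1 * w)) - 1) < tol
      w <- w1
      if (done) {
        converged[comp] <- TRUE
        break
      }
    }
    W[comp, ] <- w
  }
  list(unmix = W %*% K, center = ctr, converged = converged)
}

#' Remove the blink component by blink-segment ICA with weight transfer
#'
#' Segments the recording ±`segment_ms` around each detected blink,
#' concatenates the segments, and fits ICA on this blink-rich subset (where
#' the blink source dominates, making it identifiable even with few
#' channels). The unmixing weights are then transferred to the full
#' continuous recording; the component most correlated with the low-passed
#' frontal channel within the blink segments is zeroed, and the data are
#' remixed. Channel count, length and sampling rate are preserved.
#'
#' @param rec an `eeg_recording` (typically after [eeg_preprocess()]).
#' @param blink_indices sample indices from [detect_blinks()].
#' @param segment_ms half-window around each blink (default 500 ms).
#' @param min_blinks fewer blinks than this skips cleaning with a warning
#'   (default 5).
#' @param ica ICA engine: a function `(X) -> list(unmix, center)`; the
#'   default is the in-package symmetric FastICA.
#' @return list with `rec` (cleaned recording), `blink_component`,
#'   `component_corr`, `unmix`.
#' @export
blink_ica_clean <- function(rec, blink_indices, segment_ms = 500,
                            min_blinks = 5, ica = fastica_unmix) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(blink_indices) < min_blinks) {
    warning("fewer than ", min_blinks, " blinks; returning data unchanged")
    return(list(rec = rec, blink_component = NA_integer_,
                component_corr = NA_real_, unmix = NULL))
  }
  fs <- rec$fs_hz
  half <- round(segment_ms / 1000 * fs)
  n <- ncol(rec$data)
  seg_idx <- unique(unlist(lapply(blink_indices, function(i)
    max(1L, i - half):min(n, i + half))))
  seg_idx <- sort(seg_idx)
  fit <- ica(rec$data[, seg_idx, drop = FALSE])
  U <- fit$unmix                               # components x channels
  S_full <- U %*% (rec$data - rowMeans(rec$data))
  # identify the blink component inside the segments
  fz <- lowpass(rec$data[match("Fz", rec$channel_labels), ], fs)
  cors <- abs(stats::cor(t(S_full[, seg_idx, drop = FALSE]), fz[seg_idx]))
  bc <- which.max(cors)
  if (!is.null(fit$converged) && !fit$converged[bc])
    stop("ICA non-convergence on the blink component (unit ", bc,
         ", |corr| ", signif(max(cors), 3), "); increase max_iter or ",
         "supply a different ICA engine")
  A <- solve(U)                                # remixing matrix
  S_full[bc, ] <- 0
  cleaned <- A %*% S_full + rowMeans(rec$data)
  rec$data <- cleaned
  list(rec = rec, blink_component = bc, component_corr = max(cors),
       unmix = U)
}

#' Classify Simon-task trials
#'
#' Labels each trial correct or error by comparing the response key with
#' the key mapped to the stimulus color; responses after the response
#' window are excluded as `late`, trials without a response as `missed`.
#' A response at exactly the window boundary is included.
#'
#' @param trial_table data.frame with `color`, `response_key`, `rt_ms`
#'   (and optionally `correct_key`).
#' @param cfg a [task_config()].
#' @return the table with added `status`
#'   (`correct`/`error`/`late`/`missed`) and `included` columns.
#' @export
classify_trials <- function(trial_table, cfg = task_config()) {
  correct_key <- if ("correct_key" %in% names(trial_table))
    trial_table$correct_key else unname(cfg$key_map[trial_table$color])
  status <- ifelse(is.na(trial_table$rt_ms), "missed",
            ifelse(trial_table$rt_ms > cfg$response_window_ms, "late",
            ifelse(trial_table$response_key == correct_key,
                   "correct", "error")))
  trial_table$status <- status
  trial_table$included <- status %in% c("correct", "error")
  trial_table
}

# Welch PSD, Hann window, 50% overlap; returns list(freq, psd) with psd in
# units^2/Hz (one-sided)
welch_psd <- function(x, fs, nseg = 128) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, nseg %/% 2)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + abs(stats::fft(seg))^2 * scale
  }
  psd <- acc / length(starts)
  half <- seq_len(nseg %/% 2 + 1L)
  psd <- psd[half]
  psd[2:(length(half) - 1)] <- 2 * psd[2:(length(half) - 1)]
  list(freq = (half - 1) * fs / nseg, psd = psd)
}

#' Cut epochs around markers and apply two-stage artifact rejection
#'
#' Epochs span `window_ms` around each marker. An epoch x channel cell is
#' flagged if the absolute amplitude exceeds `volt_thresh_uv` anywhere, or
#' if the Welch band power within `spec_band_hz` exceeds `spec_thresh_db`
#' (dB re 1 µV²/Hz). An epoch is rejected if any retained channel is
#' flagged. Markers whose window falls outside the recording are dropped.
#'
#' @param rec an `eeg_recording`.
#' @param markers data.frame (`label`, `sample`, `trial`); defaults to the
#'   recording's own markers.
#' @param window_ms epoch window (default `c(-1000, 1500)` ms).
#' @param volt_thresh_uv voltage threshold (default 100 µV).
#' @param spec_thresh_db spectral threshold (default 50 dB).
#' @param spec_band_hz spectral band (default `c(20, 40)` Hz).
#' @param trial_meta optional trial table whose `congruency`/`accuracy`/
#'   `status` columns are joined by trial id.
#' @return class `epoch_set`: list with `data` (epochs x channels x time,
#'   µV), `times_ms`, `fs_hz`, `channel_labels`, `meta` (one row per
#'   epoch: `label`, `trial`, joined trial columns), `flags`
#'   (epochs x channels), `flag_reason`, `rejected`,
#'   `interpolated_channels`.
#' @export
epoch_and_reject <- function(rec, markers = rec$markers,
                             window_ms = c(-1000, 1500),
                             volt_thresh_uv = 100, spec_thresh_db = 50,
                             spec_band_hz = c(20, 40), trial_meta = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  i0 <- round(window_ms[1] / 1000 * fs)
  i1 <- round(window_ms[2] / 1000 * fs)
  n <- ncol(rec$data)
  ok <- markers$sample + i0 >= 1 & markers$sample + i1 <= n
  markers <- markers[ok, , drop = FALSE]
  n_ep <- nrow(markers)
  if (!n_ep) stop("no markers with a complete epoch window")
  n_ch <- nrow(rec$data)
  n_t <- i1 - i0 + 1L
  data <- array(NA_real_, c(n_ep, n_ch, n_t))
  for (e in seq_len(n_ep)) {
    idx <- (markers$sample[e] + i0):(markers$sample[e] + i1)
    data[e, , ] <- rec$data[, idx]
  }
  flags <- matrix(FALSE, n_ep, n_ch)
  reason <- matrix("", n_ep, n_ch)
  band <- spec_band_hz
  for (e in seq_len(n_ep)) for (ch in seq_len(n_ch)) {
    x <- data[e, ch, ]
    r <- character(0)
    if (max(abs(x)) > volt_thresh_uv) r <- "voltage"
    ps <- welch_psd(x, fs)
    inb <- ps$freq >= band[1] & ps$freq <= band[2]
    p_db <- 10 * log10(mean(ps$psd[inb]))
    if (is.finite(p_db) && p_db > spec_thresh_db) r <- c(r, "spectral")
    if (length(r)) {
      flags[e, ch] <- TRUE
      reason[e, ch] <- paste(r, collapse = "+")
    }
  }
  meta <- data.frame(label = markers$label, trial = markers$trial)
  if (!is.null(trial_meta)) {
    j <- match(meta$trial, trial_meta$trial)
    for (col in intersect(c("congruency", "accuracy", "status", "rt_ms"),
                          names(trial_meta)))
      meta[[col]] <- trial_meta[[col]][j]
  }
  structure(list(data = data, times_ms = (i0:i1) / fs * 1000, fs_hz = fs,
                 channel_labels = rec$channel_labels, meta = meta,
                 flags = flags, flag_reason = reason,
                 rejected = rowSums(flags) > 0,
                 interpolated_channels = character(0)),
            class = "epoch_set")
}

# unit-sphere coordinates for the montage (approximate standard 10-20
# positions; polar angle from the vertex, azimuth from the right ear,
# counterclockwise seen from above)
montage_positions <- function(labels = eeg_montage_labels()) {
  ang <- list(Fz = c(46, 90), C3 = c(46, 180), Cz = c(0, 0), C4 = c(46, 0),
              Pz = c(46, 270), PO7 = c(92, 234), Oz = c(92, 270),
              PO8 = c(92, 306))
  pos <- t(vapply(labels, function(l) {
    a <- ang[[l]] * pi / 180
    c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))
  }, numeric(3)))
  rownames(pos) <- labels
  pos
}

# Perrin-style spherical-spline g function on cos(angle), order m, N terms
spline_g <- function(cosang, m = 4, n_terms = 20) {
  out <- matrix(0, nrow(cosang), ncol(cosang))
  # Legendre recurrence evaluated term by term
  P_prev <- matrix(1, nrow(cosang), ncol(cosang))
  P_cur <- cosang
  for (nn in 1:n_terms) {
    if (nn > 1) {
      P_new <- ((2 * nn - 1) * cosang * P_cur - (nn - 1) * P_prev) / nn
      P_prev <- P_cur
      P_cur <- P_new
    }
    out <- out + (2 * nn + 1) / (nn^m * (nn + 1)^m) * P_cur
  }
  out / (4 * pi)
}

# reconstruct bad channels from good ones by spherical-spline interpolation
spherical_spline_interp <- function(data_ch_by_t, labels, bad, m = 4,
                                    lambda = 1e-7) {
  good <- setdiff(labels, bad)
  gi <- match(good, labels)
  pos <- montage_positions(labels)
  cg <- pos[good, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  G <- spline_g(pmin(pmax(cg, -1), 1), m)
  k <- length(good)
  A <- rbind(cbind(G + lambda * diag(k), rep(1, k)), c(rep(1, k), 0))
  V <- data_ch_by_t[gi, , drop = FALSE]
  sol <- solve(A, rbind(V, 0))
  cb <- pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  Gb <- spline_g(pmin(pmax(cb, -1), 1), m)
  Gb %*% sol[seq_len(k), , drop = FALSE] +
    matrix(sol[k + 1, ], length(bad), ncol(V), byrow = TRUE)
}

#' Channel and participant hygiene rules
#'
#' Channels flagged in more than `chan_epoch_limit` of epochs are excluded
#' and reconstructed by spherical-spline interpolation (order 4, standard
#' 10--20 unit-sphere positions) from the remaining channels, in every
#' epoch; their flags are then cleared and epoch rejection recomputed. The
#' participant is excluded if interpolated channels exceed
#' `participant_limit` of channels. Applied literally on an 8-channel
#' montage one interpolated channel is 12.5% > 10%, so any interpolation
#' excludes the participant; `participant_rule = "rounded"` instead allows
#' up to `round(limit * n_channels)` interpolated channels.
#'
#' @param es an `epoch_set`.
#' @param chan_epoch_limit fraction of epochs (default 0.20).
#' @param participant_limit fraction of channels (default 0.10).
#' @param participant_rule `"literal"` (default) or `"rounded"`.
#' @return the `epoch_set` with interpolated channels reconstructed, plus
#'   elements `participant_excluded` (logical) and
#'   `interpolated_channels`.
#' @export
channel_hygiene <- function(es, chan_epoch_limit = 0.20,
                            participant_limit = 0.10,
                            participant_rule = c("literal", "rounded")) {
  stopifnot(inherits(es, "epoch_set"))
  participant_rule <- match.arg(participant_rule)
  frac <- colMeans(es$flags)
  bad <- es$channel_labels[frac > chan_epoch_limit]
  if (length(bad)) {
    if (length(bad) >= length(es$channel_labels) - 1)
      stop("cannot interpolate: too few clean channels remain")
    bi <- match(bad, es$channel_labels)
    for (e in seq_len(dim(es$data)[1])) {
      es$data[e, bi, ] <- spherical_spline_interp(
        matrix(es$data[e, , ], dim(es$data)[2], dim(es$data)[3]),
        es$channel_labels, bad)
    }
    es$flags[, bi] <- FALSE
    es$flag_reason[, bi] <- ""
    es$rejected <- rowSums(es$flags) > 0
  }
  es$interpolated_channels <- bad
  n_ch <- length(es$channel_labels)
  es$participant_excluded <- if (participant_rule == "literal")
    length(bad) / n_ch > participant_limit
  else length(bad) > round(participant_limit * n_ch)
  es
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every epoch and channel with complex Morlet wavelets at
#' `n_freqs` linearly spaced frequencies (default 2--30 Hz in 20 steps)
#' whose cycle counts increase logarithmically (default 3 to 6 over the 20
#' steps); power is the squared magnitude, computed at the single-trial
#' level. Samples within half a wavelet length of either epoch edge are
#' flagged unreliable per frequency.
#'
#' @param es an `epoch_set`.
#' @param freq_range,n_freqs frequency grid (default 2--30 Hz, 20).
#' @param cycle_range cycles at the lowest/highest frequency (default
#'   `c(3, 6)`, log-spaced).
#' @param decim keep every `decim`-th time sample (default 4) to bound
#'   memory.
#' @param keep_epochs optional logical/integer subset of epochs.
#' @return class `tf_map`: list with `power`
#'   (epochs x channels x freqs x times, µV²), `freqs`, `cycles`,
#'   `times_ms`, `meta`, `edge_mask` (freqs x times, `TRUE` = unreliable),
#'   `channel_labels`.
#' @export
morlet_tf <- function(es, freq_range = c(2, 30), n_freqs = 20,
                      cycle_range = c(3, 6), decim = 4, keep_epochs = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  if (is.null(keep_epochs)) keep_epochs <- seq_len(dim(es$data)[1])
  data <- es$data[keep_epochs, , , drop = FALSE]
  meta <- es$meta[keep_epochs, , drop = FALSE]
  fs <- es$fs_hz
  freqs <- seq(freq_range[1], freq_range[2], length.out = n_freqs)
  cycles <- exp(seq(log(cycle_range[1]), log(cycle_range[2]),
                    length.out = n_freqs))
  n_ep <- dim(data)[1]; n_ch <- dim(data)[2]; n_t <- dim(data)[3]
  t_keep <- seq(1L, n_t, by = decim)
  power <- array(NA_real_, c(n_ep, n_ch, n_freqs, length(t_keep)))
  edge <- matrix(FALSE, n_freqs, length(t_keep))
  for (fi in seq_len(n_freqs)) {
    f <- freqs[fi]
    sd_t <- cycles[fi] / (2 * pi * f)
    hw <- ceiling(3.5 * sd_t * fs)            # half-width in samples
    tt <- (-hw:hw) / fs
    wav <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    wav <- wav / sqrt(sum(Mod(wav)^2))        # unit energy
    nconv <- n_t + length(wav) - 1L
    nfft <- stats::nextn(nconv, 2)
    wf <- stats::fft(c(wav, complex(real = numeric(nfft - length(wav)))))
    edge[fi, ] <- (t_keep <= hw) | (t_keep > n_t - hw)
    for (ch in seq_len(n_ch)) {
      X <- t(matrix(data[, ch, ], n_ep, n_t))  # time x epochs
      Xp <- rbind(X, matrix(0, nfft - n_t, n_ep))
      conv <- stats::mvfft(stats::mvfft(Xp) * wf, inverse = TRUE) / nfft
      res <- conv[hw + seq_len(n_t), , drop = FALSE]
      power[, ch, fi, ] <- t(Mod(res[t_keep, , drop = FALSE])^2)
    }
  }
  structure(list(power = power, freqs = freqs, cycles = cycles,
                 times_ms = es$times_ms[t_keep], meta = meta,
                 edge_mask = edge, channel_labels = es$channel_labels),
            class = "tf_map")
}

#' Divisive dB baseline normalization of a time-frequency map
#'
#' Each trial's power (per channel and frequency) is divided by the mean
#' power of that same trial's *stimulus-locked* epoch over the baseline
#' window, then expressed as `10 * log10(power / baseline)`. Response-locked
#' epochs inherit the baseline of their own trial's stimulus-locked epoch,
#' so stimulus- and response-locked maps share a common per-trial
#' reference. Condition averages should be computed after this single-trial
#' normalization.
#'
#' @param tf a `tf_map` containing stimulus-locked epochs (and optionally
#'   response-locked epochs with matching `trial` ids).
#' @param baseline_ms baseline window relative to stimulus onset (default
#'   `c(-400, -100)` ms).
#' @return the `tf_map` with `power` replaced by dB values (`power_db`
#'   semantics) and a `baseline_ms` element.
#' @export
baseline_normalize <- function(tf, baseline_ms = c(-400, -100)) {
  stopifnot(inherits(tf, "tf_map"))
  bl_idx <- which(tf$times_ms >= baseline_ms[1] & tf$times_ms <= baseline_ms[2])
  if (!length(bl_idx)) stop("baseline window outside epoch times")
  stim <- which(tf$meta$label == "stimulus")
  if (!length(stim)) stop("no stimulus-locked epochs to take baselines from")
  # per-trial baseline: channels x freqs, from the stimulus-locked epoch
  bl_by_trial <- list()
  for (e in stim)
    bl_by_trial[[as.character(tf$meta$trial[e])]] <-
      apply(tf$power[e, , , bl_idx, drop = FALSE], c(2, 3), mean)
  out <- tf$power
  for (e in seq_len(dim(tf$power)[1])) {
    bl <- bl_by_trial[[as.character(tf$meta$trial[e])]]
    if (is.null(bl)) {
      out[e, , , ] <- NA_real_
      next
    }
    for (ti in seq_len(dim(out)[4]))
      out[e, , , ti] <- 10 * log10(tf$power[e, , , ti] / bl)
  }
  tf$power <- out
  tf$baseline_ms <- baseline_ms
  tf$normalized <- TRUE
  tf
}

#' Average a normalized time-frequency map within conditions
#'
#' @param tf a (typically baseline-normalized) `tf_map`.
#' @param lock epoch lock to select (`"stimulus"` or `"response"`).
#' @param by metadata column defining conditions (default `"accuracy"`).
#' @return named list of channel x freq x time arrays, one per condition.
#' @export
tf_condition_average <- function(tf, lock = "response", by = "accuracy") {
  sel <- which(tf$meta$label == lock & !is.na(tf$meta[[by]]))
  conds <- unique(tf$meta[[by]][sel])
  out <- list()
  for (cc in conds) {
    e <- sel[tf$meta[[by]][sel] == cc]
    out[[cc]] <- apply(tf$power[e, , , , drop = FALSE], c(2, 3, 4), mean,
                       na.rm = TRUE)
  }
  out
}
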