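#' Simon-task configuration
#'
#' @param stim_duration_ms stimulus presentation time (default 200 ms).
#' @param response_window_ms response window from stimulus onset (default
#'   500 ms; later responses are recorded but excluded as late).
#' @param rsi_ms jittered response-stimulus interval range (default
#'   800--1200 ms, starting after the response window).
#' @param trials_per_block trials per block (default 160).
#' @param key_map named character vector mapping stimulus color to the
#'   correct response key.
#' @return class `task_config`.
#' @export
task_config <- function(stim_duration_ms = 200, response_window_ms = 500,
                        rsi_ms = c(800, 1200), trials_per_block = 160,
                        key_map = c(red = "2", green = "8")) {
  if (response_window_ms < stim_duration_ms)
    stop("response window must cover the stimulus duration")
  if (any(rsi_ms <= 0)) stop("RSI range must be positive")
  structure(list(stim_duration_ms = stim_duration_ms,
                 response_window_ms = response_window_ms, rsi_ms = rsi_ms,
                 trials_per_block = trials_per_block, key_map = key_map),
            class = "task_config")
}

#' EEG recording container
#'
#' @param data channels x samples matrix in microvolts.
#' @param channel_labels channel names (default the 8-channel montage
#'   Fz, C3, Cz, C4, Pz, PO7, Oz, PO8).
#' @param fs_hz sampling rate (default 250 Hz).
#' @param markers data.frame with `label` ("stimulus"/"response"), `sample`
#'   (1-based index), `trial`.
#' @return class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels = eeg_montage_labels(),
                          fs_hz = 250, markers = NULL) {
  if (nrow(data) != length(channel_labels))
    stop("data must have one row per channel")
  if (!is.null(markers) && nrow(markers) &&
      (any(markers$sample < 1) || any(markers$sample > ncol(data))))
    stop("marker indices outside the recording")
  structure(list(data = data, channel_labels = channel_labels,
                 fs_hz = fs_hz, markers = markers), class = "eeg_recording")
}

#' The 8-channel montage labels
#' @export
eeg_montage_labels <- function() c("Fz", "C3", "Cz", "C4", "Pz", "PO7", "Oz", "PO8")

# 1/f ("pink") noise via spectral shaping, sd scaled to `sd`
pink_noise <- function(n, sd = 1) {
  nf <- stats::nextn(n, 2)
  w <- stats::rnorm(nf)
  W <- stats::fft(w)
  f <- c(1, seq_len(nf - 1))               # avoid 0 at DC
  f <- pmin(f, nf - f + 1)                  # symmetric about Nyquist
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)]
  sd * (x - mean(x)) / stats::sd(x)
}

# rank-1 spatial patterns over the montage (Fz C3 Cz C4 Pz PO7 Oz PO8).
# The ocular dipole sits far anterior, so the blink falls off steeply from
# Fz backwards (>4:1); error-related frontal-midline theta peaks at Cz/FCz;
# posterior alpha peaks occipitally. Keeping these patterns spatially
# distinct is what makes blink-component removal separable from midline
# theta, as it is in real recordings.
blink_topography <- function() c(1, 0.30, 0.35, 0.30, 0.12, 0.05, 0.04, 0.05)
theta_topography <- function() c(0.85, 0.45, 1, 0.45, 0.5, 0.2, 0.15, 0.2)
alpha_topography <- function() c(0.1, 0.2, 0.2, 0.2, 0.6, 0.9, 1, 0.9)

#' Generate a synthetic Simon-task EEG session
#'
#' Builds an 8-channel, 250 Hz recording containing pink-noise background,
#' 10 Hz posterior alpha, stereotyped frontal-dominant blink transients
#' (300 ms raised cosine, amplitude falling off roughly 4:1 from Fz to the
#' posterior sites), and — on error trials only — a 6 Hz theta burst over
#' 0--400 ms after the response, with frontal-midline topography. Stimulus
#' and response markers are embedded, and the trial table carries stimulus
#' color/side, the response key, congruency, accuracy, and RT. Reaction
#' times follow a truncated log-normal within the response window; a
#' configurable fraction of responses land after the window (late) or are
#' omitted (missed).
#'
#' @param cfg a [task_config()].
#' @param n_blocks number of 160-trial blocks (default 1).
#' @param error_rate probability a responded trial is an error.
#' @param theta_amp_uv peak amplitude of the error theta burst at Fz (µV).
#' @param blink_rate_hz mean blink rate (default 0.2 Hz; 0 disables).
#' @param blink_amp_uv blink amplitude at Fz (default 80 µV).
#' @param noise_sd_uv pink-noise SD per channel (default 8 µV).
#' @param alpha_amp_uv posterior alpha amplitude (default 4 µV).
#' @param late_prob,miss_prob probability of a late / missing response.
#' @param seed RNG seed.
#' @return list with `rec` (an [eeg_recording()]), `trials` (data.frame),
#'   and ground truth `blink_times_s`, `theta_trials` (trial ids carrying a
#'   burst).
#' @export
synth_eeg_simon <- function(cfg = task_config(), n_blocks = 1,
                            error_rate = 0.1, theta_amp_uv = 6,
                            blink_rate_hz = 0.2, blink_amp_uv = 80,
                            noise_sd_uv = 8, alpha_amp_uv = 4,
                            late_prob = 0.03, miss_prob = 0.02, seed = 1) {
  set.seed(seed)
  fs <- 250
  n_trials <- n_blocks * cfg$trials_per_block
  rw_s <- cfg$response_window_ms / 1000

  # trial schedule
  t_stim <- numeric(n_trials)
  rt_s <- rep(NA_real_, n_trials)
  t_cur <- 2.0                                 # lead-in
  for (i in seq_len(n_trials)) {
    t_stim[i] <- t_cur
    kind <- sample(c("ok", "late", "miss"), 1,
                   prob = c(1 - late_prob - miss_prob, late_prob, miss_prob))
    rt_s[i] <- switch(kind,
      ok = {
        r <- stats::rlnorm(1, meanlog = log(0.33), sdlog = 0.22)
        while (r > rw_s - 0.002) r <- stats::rlnorm(1, log(0.33), 0.22)
        r
      },
      late = stats::runif(1, rw_s + 0.02, rw_s + 0.25),
      miss = NA_real_)
    rsi <- stats::runif(1, cfg$rsi_ms[1], cfg$rsi_ms[2]) / 1000
    t_cur <- t_cur + rw_s + rsi
  }
  dur_s <- t_cur + 2.0
  n <- ceiling(dur_s * fs)

  color <- sample(names(cfg$key_map), n_trials, replace = TRUE)
  side <- sample(c("left", "right"), n_trials, replace = TRUE)
  correct_key <- unname(cfg$key_map[color])
  responded <- !is.na(rt_s)
  is_err <- responded & stats::runif(n_trials) < error_rate
  other_key <- vapply(correct_key, function(k)
    setdiff(unname(cfg$key_map), k)[1], character(1))
  resp_key <- ifelse(responded, ifelse(is_err, other_key, correct_key), NA)
  # congruency: correct-response side matches stimulus side
  key_side <- c("2" = "left", "8" = "right")
  congruency <- ifelse(key_side[correct_key] == side, "congruent",
                       "incongruent")

  trials <- data.frame(
    trial = seq_len(n_trials), block = rep(seq_len(n_blocks),
                                           each = cfg$trials_per_block),
    color = color, side = side, congruency = congruency,
    response_key = resp_key, correct_key = correct_key,
    rt_ms = rt_s * 1000, accuracy = ifelse(!responded, NA,
                                           ifelse(is_err, "error", "correct")))

  # signal
  data <- matrix(0, 8, n)
  for (ch in 1:8) data[ch, ] <- pink_noise(n, noise_sd_uv)
  tvec <- (seq_len(n) - 1) / fs
  alpha <- alpha_amp_uv * sin(2 * pi * 10 * tvec + stats::runif(1, 0, 2 * pi)) *
    (1 + 0.3 * sin(2 * pi * 0.1 * tvec))
  data <- data + outer(alpha_topography(), alpha)

  blink_times <- numeric(0)
  if (blink_rate_hz > 0) {
    tb <- 1.0
    while (TRUE) {
      tb <- tb + 1.0 + stats::rexp(1, blink_rate_hz)
      if (tb > dur_s - 1) break
      blink_times <- c(blink_times, tb)
    }
    bl_len <- round(0.3 * fs)
    shape <- blink_amp_uv * 0.5 * (1 - cos(2 * pi * seq_len(bl_len) / bl_len))
    topo <- blink_topography()
    for (tb in blink_times) {
      i0 <- round(tb * fs)
      idx <- i0:(i0 + bl_len - 1)
      data[, idx] <- data[, idx] + outer(topo, shape)
    }
  }

  stim_idx <- round(t_stim * fs) + 1L
  resp_idx <- ifelse(responded, round((t_stim + rt_s) * fs) + 1L, NA)
  theta_trials <- which(is_err & responded)
  if (theta_amp_uv > 0 && length(theta_trials)) {
    th_len <- round(0.4 * fs)
    hann <- 0.5 * (1 - cos(2 * pi * seq_len(th_len) / th_len))
    topo <- theta_topography()
    for (i in theta_trials) {
      i0 <- resp_idx[i]
      idx <- i0:(i0 + th_len - 1)
      ph <- stats::runif(1, 0, 2 * pi)
      burst <- theta_amp_uv * hann * sin(2 * pi * 6 * (seq_len(th_len) / fs) + ph)
      data[, idx] <- data[, idx] + outer(topo, burst)
    }
  }

  markers <- rbind(
    data.frame(label = "stimulus", sample = stim_idx, trial = seq_len(n_trials)),
    data.frame(label = "response", sample = resp_idx[responded],
               trial = which(responded)))
  markers <- markers[order(markers$sample), ]
  rownames(markers) <- NULL

  # ground truth records the blink *peak* times (center of the 300 ms
  # raised cosine), which is what a peak detector marks
  list(rec = eeg_recording(data, fs_hz = fs, markers = markers),
       trials = trials, blink_times_s = blink_times + 0.15,
       theta_trials = theta_trials)
}
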