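# one shared seeded Simon session keeps the EEG tests fast
simon <- synth_eeg_simon(n_blocks = 1, seed = 7, theta_amp_uv = 8)
rec_f <- eeg_preprocess(simon$rec)

test_that("band-pass preprocessing keeps the passband and kills the edges", {
  fs <- 250
  n <- 10 * fs
  t <- (0:(n - 1)) / fs
  mk <- function(x) eeg_recording(matrix(rep(x, 8), 8, n, byrow = TRUE),
                                  fs_hz = fs)
  mid <- function(y) y[(2 * fs):(8 * fs)]          # avoid filter edges
  amp <- function(y) sqrt(2 * mean(mid(y)^2))

  hf <- eeg_preprocess(mk(10 * sin(2 * pi * 50 * t)))
  expect_lt(amp(hf$data[1, ]), 1)                  # >= 90% attenuation

  pb <- eeg_preprocess(mk(10 * sin(2 * pi * 10 * t)))
  expect_equal(amp(pb$data[1, ]), 10, tolerance = 0.5)

  dc <- eeg_preprocess(mk(rep(25, n) + rnorm(n)))
  expect_lt(abs(mean(dc$data[1, ])), 0.5)
})

test_that("blink detection matches the injected blink times", {
  bl <- detect_blinks(rec_f)
  m <- match_events(bl / 250, simon$blink_times_s, 0.04)
  expect_gte(m$true_pos / length(simon$blink_times_s), 0.9)
  expect_lte(m$false_pos, 2)

  # scale robustness: doubled amplitudes give the same detections
  rec2 <- rec_f
  rec2$data <- rec2$data * 2
  expect_identical(detect_blinks(rec2), bl)

  clean <- synth_eeg_simon(n_blocks = 1, blink_rate_hz = 0, seed = 8)
  expect_length(detect_blinks(eeg_preprocess(clean$rec)), 0)
})

test_that("blink-segment ICA removes blinks but spares posterior alpha", {
  fs <- 250
  bl <- detect_blinks(rec_f)
  cl <- blink_ica_clean(rec_f, bl)
  expect_equal(dim(cl$rec$data), dim(rec_f$data))
  expect_equal(cl$rec$fs_hz, rec_f$fs_hz)

  idx <- unique(unlist(lapply(simon$blink_times_s, function(tb) {
    i <- round(tb * fs); max(1, i - 125):min(ncol(rec_f$data), i + 125)
  })))
  blink_band_power <- function(x)
    mean(signal::filtfilt(signal::butter(4, 4 / (fs / 2), "low"), x)[idx]^2)
  reduction <- 1 - blink_band_power(cl$rec$data[1, ]) /
    blink_band_power(rec_f$data[1, ])
  expect_gte(reduction, 0.8)

  alpha_power <- function(x) {
    p <- physiofuse:::welch_psd(x, fs, 512)
    mean(p$psd[p$freq >= 9 & p$freq <= 11])
  }
  oz <- match("Oz", rec_f$channel_labels)
  rel_change <- abs(alpha_power(cl$rec$data[oz, ]) /
                      alpha_power(rec_f$data[oz, ]) - 1)
  expect_lt(rel_change, 0.1)

  # zero blinks: recording returned unchanged with a warning
  expect_warning(same <- blink_ica_clean(rec_f, integer(0)), "blinks")
  expect_identical(same$rec$data, rec_f$data)
})

test_that("trial classification applies the response-window boundary", {
  cfg <- task_config()
  tt <- data.frame(color = c("red", "red", "red", "red"),
                   response_key = c("2", "2", "8", NA),
                   rt_ms = c(499, 501, 430, NA))
  out <- classify_trials(tt, cfg)
  expect_equal(out$status, c("correct", "late", "error", "missed"))
  expect_equal(out$included, c(TRUE, FALSE, TRUE, FALSE))

  # boundary value exactly at the window is included
  out2 <- classify_trials(data.frame(color = "green", response_key = "8",
                                     rt_ms = 500), cfg)
  expect_equal(out2$status, "correct")

  sim <- classify_trials(simon$trials, cfg)
  expect_equal(nrow(sim), 160)
  n_err <- sum(sim$status == "error")
  expect_true(n_err >= 8 && n_err <= 26)          # ~16 at error rate 0.1
  expect_true(all(sim$status[is.na(sim$rt_ms)] == "missed"))
  expect_true(all(sim$rt_ms[sim$status == "late"] > 500))
})

test_that("epoch rejection flags voltage spikes and high-band bursts", {
  fs <- 250
  n <- 20 * fs
  set.seed(33)
  base <- matrix(rnorm(8 * n, 0, 5), 8, n)
  markers <- data.frame(label = "stimulus", sample = c(2, 6, 10, 14) * fs,
                        trial = 1:4)
  # epoch 2: a 150 uV spike on C3; epoch 3: a strong 30 Hz burst on Pz
  base[2, 6 * fs + 25] <- 150
  tt <- (0:(n - 1)) / fs
  burst_amp <- sqrt(2 * 40 * 10^(51 / 10))        # ~51 dB re 1 uV^2/Hz band mean
  win <- tt >= 10 & tt < 11.5
  base[5, win] <- base[5, win] + burst_amp * sin(2 * pi * 30 * tt[win])
  rec <- eeg_recording(base, fs_hz = fs, markers = markers)
  es <- epoch_and_reject(rec, window_ms = c(-1000, 1500))
  expect_equal(dim(es$data)[3], length(seq(-250, 375)))
  expect_false(es$rejected[1])
  expect_true(es$rejected[2])
  expect_match(es$flag_reason[2, 2], "voltage")
  expect_true(es$rejected[3])
  expect_match(es$flag_reason[3, 5], "spectral")
  expect_false(es$rejected[4])
})

test_that("channel hygiene interpolates bad channels and rules on the participant", {
  fs <- 250
  n <- 30 * fs
  set.seed(34)
  base <- matrix(rnorm(8 * n, 0, 5), 8, n)
  # PO7 (ch 6) carries spikes in 3 of 10 epochs (30% > 20%)
  markers <- data.frame(label = "stimulus",
                        sample = seq(2, 29, 3) * fs, trial = 1:10)
  for (k in 1:3) base[6, (2 + 3 * (k - 1)) * fs + 10] <- 300
  rec <- eeg_recording(base, fs_hz = fs, markers = markers)
  es <- epoch_and_reject(rec, window_ms = c(-500, 500))
  expect_true(all(which(colMeans(es$flags) > 0.2) == 6))
  hy <- channel_hygiene(es)
  expect_equal(hy$interpolated_channels, "PO7")
  # interpolated channel is rebuilt within plausible amplitude bounds
  expect_lt(max(abs(hy$data[, 6, ])), 100)
  expect_false(any(hy$flags[, 6]))
  # literal 10% rule: 1 of 8 channels = 12.5% excludes the participant
  expect_true(hy$participant_excluded)
  # montage-aware variant tolerates a single interpolated channel
  hy2 <- channel_hygiene(es, participant_rule = "rounded")
  expect_false(hy2$participant_excluded)

  # no channel above the limit: nothing interpolated, participant retained
  clean <- epoch_and_reject(eeg_recording(matrix(rnorm(8 * n, 0, 5), 8, n),
                                          fs_hz = fs, markers = markers),
                            window_ms = c(-500, 500))
  hc <- channel_hygiene(clean)
  expect_length(hc$interpolated_channels, 0)
  expect_false(hc$participant_excluded)
})

test_that("spherical-spline interpolation reconstructs smooth scalp fields", {
  # a field linear in electrode position is recovered well at the bad site
  pos <- physiofuse:::montage_positions()
  field <- 10 + 20 * pos[, 2] + 15 * pos[, 3]
  X <- matrix(rep(field, 10), 8, 10)
  rebuilt <- physiofuse:::spherical_spline_interp(X, rownames(pos), "Cz")
  expect_equal(unname(rebuilt[1, 1]), unname(field["Cz"]), tolerance = 1.5)
})

test_that("Morlet maps localize frequency and scale quadratically", {
  fs <- 250
  n_t <- 626
  t <- (seq_len(n_t) - 251) / fs
  mk_es <- function(amp) {
    dat <- array(rnorm(2 * 8 * n_t, 0, 0.01), c(2, 8, n_t))
    for (e in 1:2) for (ch in 1:8)
      dat[e, ch, ] <- dat[e, ch, ] + amp * sin(2 * pi * 17 * t)
    structure(list(data = dat, times_ms = t * 1000, fs_hz = fs,
                   channel_labels = eeg_montage_labels(),
                   meta = data.frame(label = "stimulus", trial = 1:2),
                   flags = matrix(FALSE, 2, 8),
                   flag_reason = matrix("", 2, 8),
                   rejected = c(FALSE, FALSE),
                   interpolated_channels = character(0)),
              class = "epoch_set")
  }
  tf1 <- morlet_tf(mk_es(1), decim = 2)
  mid <- !tf1$edge_mask[10, ]
  prof <- vapply(seq_along(tf1$freqs), function(fi)
    mean(tf1$power[1, 1, fi, !tf1$edge_mask[fi, ]]), numeric(1))
  expect_equal(which.max(prof), which.min(abs(tf1$freqs - 17)))

  tf2 <- morlet_tf(mk_es(2), decim = 2)
  pk <- which.max(prof)
  r <- mean(tf2$power[1, 1, pk, mid]) / mean(tf1$power[1, 1, pk, mid])
  expect_equal(r, 4, tolerance = 0.05)
})

test_that("white-noise epochs show no systematic temporal power structure", {
  set.seed(35)
  n_t <- 626
  dat <- array(rnorm(40 * 8 * n_t, 0, 1), c(40, 8, n_t))
  es <- structure(list(data = dat, times_ms = seq(-1000, 1500, by = 4),
                       fs_hz = 250, channel_labels = eeg_montage_labels(),
                       meta = data.frame(label = "stimulus", trial = 1:40),
                       flags = matrix(FALSE, 40, 8),
                       flag_reason = matrix("", 40, 8),
                       rejected = rep(FALSE, 40),
                       interpolated_channels = character(0)),
                  class = "epoch_set")
  tf <- morlet_tf(es, decim = 4)
  fi <- 10
  # pool epochs and (independent) channels; any event-locked structure
  # would survive the pooling, sampling noise largely averages out
  prof <- apply(tf$power[, , fi, !tf$edge_mask[fi, ]], 3, mean)
  expect_lt(diff(range(prof)) / mean(prof), 0.5)
})

test_that("divisive dB baseline maps the baseline window to zero", {
  sim2 <- simon
  rec2 <- blink_ica_clean(rec_f, detect_blinks(rec_f))$rec
  trials <- classify_trials(sim2$trials)
  es <- epoch_and_reject(rec2, trial_meta = trials)
  keep <- which(!es$rejected)[1:20]
  tf <- morlet_tf(es, keep_epochs = keep, decim = 8)
  tfn <- baseline_normalize(tf)
  bl <- tfn$times_ms >= -400 & tfn$times_ms <= -100
  stim_e <- which(tfn$meta$label == "stimulus")
  for (e in stim_e[1:5]) {
    lin <- 10^(tfn$power[e, 3, 7, bl] / 10)
    expect_equal(mean(lin), 1, tolerance = 1e-9)
  }
  # closed form: doubling power is ~3.01 dB
  expect_equal(10 * log10(2), 3.0103, tolerance = 1e-4)
})

test_that("post-response theta contrast is positive and grows with burst amplitude", {
  theta_contrast <- function(amp) {
    sim <- synth_eeg_simon(n_blocks = 1, seed = 9, theta_amp_uv = amp,
                           error_rate = 0.15)
    rec <- eeg_preprocess(sim$rec)
    cl <- blink_ica_clean(rec, detect_blinks(rec))
    trials <- classify_trials(sim$trials)
    es <- epoch_and_reject(cl$rec, trial_meta = trials)
    inc <- trials$trial[trials$included]
    sel <- which(es$meta$trial %in% inc & !es$rejected)
    both <- intersect(es$meta$trial[sel][es$meta$label[sel] == "stimulus"],
                      es$meta$trial[sel][es$meta$label[sel] == "response"])
    err <- intersect(both, sim$theta_trials)
    cor_t <- head(setdiff(both, sim$theta_trials), 25)
    sel <- sel[es$meta$trial[sel] %in% c(err, cor_t)]
    tfn <- baseline_normalize(morlet_tf(es, keep_epochs = sel, decim = 8))
    avg <- tf_condition_average(tfn, lock = "response", by = "accuracy")
    roi_f <- tfn$freqs >= 4 & tfn$freqs <= 7
    roi_t <- tfn$times_ms >= 0 & tfn$times_ms <= 400
    roi_ch <- c(1, 3)                              # frontal-midline Fz, Cz
    mean(avg$error[roi_ch, roi_f, roi_t]) -
      mean(avg$correct[roi_ch, roi_f, roi_t])
  }
  c_small <- theta_contrast(5)
  c_large <- theta_contrast(12)
  expect_gt(c_small, 0)
  expect_gt(c_large, c_small)
})
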