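test_that("protocol templates expand to contiguous labeled timelines", {
  tl <- make_timeline(protocol_template("occlusion"), start_ns = 0)
  expect_equal(nrow(tl), 5)
  expect_equal(timeline_duration_s(tl), 660)
  expect_equal((tl$end_ns - tl$start_ns) / 1e9, c(180, 60, 60, 60, 300))

  one <- flat_timeline(60)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start_ns, one$end_ns), c(0, 60e9))

  ex <- make_timeline(protocol_template("exercise"))
  # contiguity forced: each phase ends exactly where the next begins
  expect_equal(ex$end_ns[-5], ex$start_ns[-1])

  expect_error(protocol_template(phases = data.frame(
    label = "x", duration_s = 0)), "duration")
  expect_error(protocol_template(phases = data.frame(
    label = c("a", "a"), duration_s = c(1, 1))), "unique")
})

test_that("HR trajectory relaxes exponentially toward phase-zone targets", {
  ex <- make_timeline(protocol_template("exercise"))
  # tau -> 0 snaps to the target immediately
  tr0 <- simulate_hr_trajectory(ex, 60, 200, tau_s = 0)
  mod <- phase_at(ex, round(tr0$times_s * 1e9)) == "moderate"
  expect_equal(tr0$hr_bpm[mod], rep(130, sum(mod)))  # 65% midpoint of 200

  # rest only: constant at hr_rest
  tr_rest <- simulate_hr_trajectory(flat_timeline(120, "rest"), 55, 190)
  expect_true(all(tr_rest$hr_bpm == 55))

  # closed form: after t >> tau the moderate phase approaches 130 bpm
  tr <- simulate_hr_trajectory(ex, 60, 200, tau_s = 10)
  end_mod <- max(which(mod))
  expect_equal(tr$hr_bpm[end_mod], 130, tolerance = 1e-3)
  # continuity at phase boundaries
  expect_lt(max(abs(diff(tr$hr_bpm))), 1.5)
  expect_true(all(tr$hr_bpm >= 30 & tr$hr_bpm <= 220))
})

test_that("synthetic ECG places beats at the integrated rate", {
  tr <- simulate_hr_trajectory(flat_timeline(60, "rest"), 60, 190)
  e <- synth_ecg(tr, noise_sd = 0, seed = 1)
  expect_true(abs(length(e$beat_times_s) - 60) <= 1)
  expect_equal(diff(e$beat_times_s), rep(1, length(e$beat_times_s) - 1),
               tolerance = 1e-6)
  # noise-free: R amplitude at each beat equals the template amplitude
  amp <- stream_approx(e$stream, e$beat_times_s)
  expect_equal(amp, rep(amp[1], length(amp)), tolerance = 0.02)
  expect_true(all(diff(e$stream$timestamps_ns) > 0))
  expect_true(all(is.finite(e$stream$values)))
})

test_that("motion segments raise within-phase ECG variance", {
  tr <- simulate_hr_trajectory(flat_timeline(120, "rest"), 60, 190)
  seg <- data.frame(start_s = 60, end_s = 120, factor = 5)
  e <- synth_ecg(tr, noise_sd = 0.02, motion_segments = seg, seed = 4)
  t_s <- (e$stream$timestamps_ns - e$stream$timestamps_ns[1]) / 1e9
  v_clean <- var(e$stream$values[t_s < 60])
  v_motion <- var(e$stream$values[t_s >= 60])
  expect_gt(v_motion, v_clean)
})

test_that("device HR model applies bias, jitter and dropout as configured", {
  tr <- simulate_hr_trajectory(flat_timeline(300, "rest"), 70, 190)
  clean <- synth_device_hr(tr, device_error_model(1, 0, 0, 0, 0), seed = 1)
  expect_equal(clean$values, hr_at(tr, (clean$timestamps_ns) / 1e9))

  biased <- synth_device_hr(tr, device_error_model(1, bias_bpm = 5,
                                                   jitter_sd = 0.5), seed = 2)
  truth <- hr_at(tr, biased$timestamps_ns / 1e9)
  expect_equal(mean(biased$values - truth), 5, tolerance = 0.2)

  gone <- synth_device_hr(tr, device_error_model(1, dropout_prob = 1), seed = 3)
  expect_equal(stream_length(gone), 0)
})

test_that("StO2 occlusion kinetics are pressure-proportional and recover", {
  otl <- make_timeline(protocol_template("occlusion"))
  flat <- synth_sto2_occlusion(otl, kinetics = list(desat_rate = 0),
                               seed = 1)
  expect_true(all(flat$values == 70))

  st <- synth_sto2_occlusion(otl, seed = 1)
  ph <- phase_at(otl, st$timestamps_ns)
  slope_of <- function(lab) {
    i <- which(ph == lab)
    unname(coef(lm(st$values[i] ~ I(st$timestamps_ns[i] / 1e9)))[2])
  }
  expect_lt(slope_of("occ_200"), slope_of("occ_100"))  # steeper desat
  # recovery returns to within 1% of baseline after 5 min (tau = 30 s)
  expect_equal(st$values[stream_length(st)], 70, tolerance = 0.7)
  expect_true(all(st$values >= 0 & st$values <= 100))
})

test_that("streamed/cached split drops gap samples and shifts the cache", {
  s <- random_stream(1, 120, jitter = 0)
  both <- split_streamed_cached(s, NULL, 0)
  expect_identical(both$streamed$values, s$values)
  expect_identical(both$cached$timestamps_ns, s$timestamps_ns)

  off <- split_streamed_cached(s, NULL, 2.5)
  expect_true(all(off$cached$timestamps_ns - s$timestamps_ns == 2.5e9))

  gap <- split_streamed_cached(s, data.frame(start_s = 30, end_s = 60), 0)
  expect_equal(stream_length(gap$streamed), stream_length(s) - 30)
})

test_that("same seed reproduces a session bit-identically", {
  tr <- simulate_hr_trajectory(flat_timeline(30, "rest"), 60, 190)
  a <- synth_ecg(tr, noise_sd = 0.1, seed = 11)
  b <- synth_ecg(tr, noise_sd = 0.1, seed = 11)
  c <- synth_ecg(tr, noise_sd = 0.1, seed = 12)
  expect_identical(a$stream$values, b$stream$values)
  expect_false(identical(a$stream$values, c$stream$values))
})

test_that("Simon-task generator emits the configured trial structure", {
  sim <- synth_eeg_simon(n_blocks = 1, seed = 5)
  expect_equal(nrow(sim$trials), 160)
  expect_equal(nrow(sim$rec$data), 8)
  expect_equal(sim$rec$fs_hz, 250)
  expect_true(all(sim$rec$markers$sample >= 1 &
                    sim$rec$markers$sample <= ncol(sim$rec$data)))
  # error_rate 0: no theta bursts injected
  sim0 <- synth_eeg_simon(n_blocks = 1, error_rate = 0, seed = 5)
  expect_length(sim0$theta_trials, 0)
})

test_that("without blinks the frontal channel is as heavy-tailed as the rest", {
  sim <- synth_eeg_simon(n_blocks = 1, blink_rate_hz = 0, theta_amp_uv = 0,
                         seed = 6)
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2
  k_fz <- kurt(sim$rec$data[1, ])
  k_cz <- kurt(sim$rec$data[3, ])
  expect_equal(k_fz, k_cz, tolerance = 0.25)
  # and with blinks Fz becomes markedly more kurtotic
  simb <- synth_eeg_simon(n_blocks = 1, blink_rate_hz = 0.3, seed = 6)
  expect_gt(kurt(simb$rec$data[1, ]), k_fz + 1)
})
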