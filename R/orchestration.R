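#' Run configuration for the end-to-end pipeline
#'
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param protocol `"exercise"` or `"occlusion"` (the EEG stage runs in
#'   either case unless disabled).
#' @param out_dir output directory (created if needed).
#' @param include_eeg run the EEG cognitive stage (default `TRUE`).
#' @param eeg_blocks Simon-task blocks for the EEG stage (default 1).
#' @param overrides named list of module parameter overrides (currently
#'   `hr_rest`, `hr_max`, `ecg_noise_sd`, `clock_offset_s`, `dropout_start_s`,
#'   `dropout_len_s`, `device_bias_bpm`, `device_jitter_sd`).
#' @return class `run_config`.
#' @export
run_config <- function(seed = 1, protocol = c("exercise", "occlusion"),
                       out_dir = tempfile("physiofuse_run_"),
                       include_eeg = TRUE, eeg_blocks = 1,
                       overrides = list()) {
  protocol <- match.arg(protocol)
  defaults <- list(hr_rest = 62, hr_max = 190, ecg_noise_sd = 0.05,
                   clock_offset_s = 2.5, dropout_start_s = 300,
                   dropout_len_s = 30, device_bias_bpm = 1.5,
                   device_jitter_sd = 1.5)
  structure(list(seed = seed, protocol = protocol, out_dir = out_dir,
                 include_eeg = include_eeg, eeg_blocks = eeg_blocks,
                 params = utils::modifyList(defaults, overrides)),
            class = "run_config")
}

write_report <- function(obj, path, cfg) {
  obj$provenance <- list(seed = cfg$seed, protocol = cfg$protocol,
                         params = cfg$params,
                         package_version =
                           as.character(utils::packageVersion("physiofuse")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  path
}

#' Run the full mock-dive pipeline
#'
#' Chains simulate → fuse → align → hr → agree → sto2-qc → eeg on a
#' synthetic session and writes every artifact (CSV streams, session file,
#' JSON reports) plus a manifest with MD5 checksums to the output
#' directory. Given the same configuration the run is deterministic and the
#' manifest checksums are byte-identical.
#'
#' @param cfg a [run_config()].
#' @return the manifest (invisibly also written as `manifest.json`): list
#'   with `files` (name, md5), `stages`, and the configuration.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$protocol)) stop("config validation: protocol is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  seeds <- cfg$seed * 13L + c(ecg = 1L, dev = 2L, sto2 = 3L, eeg = 4L)
  seeds <- seeds %% .Machine$integer.max
  stages <- list()
  out <- function(f) file.path(cfg$out_dir, f)

  # --- simulate -------------------------------------------------------
  tl <- make_timeline(protocol_template("exercise"))
  traj <- simulate_hr_trajectory(tl, hr_rest = p$hr_rest, hr_max = p$hr_max)
  motion <- data.frame(start_s = tl$start_ns[2:4] / 1e9,
                       end_s = tl$end_ns[2:4] / 1e9, factor = c(1, 2, 3))
  ecg <- synth_ecg(traj, noise_sd = p$ecg_noise_sd, motion_segments = motion,
                   seed = seeds[["ecg"]])
  dev_model <- device_error_model(reporting_rate_hz = 1,
                                  bias_bpm = p$device_bias_bpm,
                                  jitter_sd = p$device_jitter_sd,
                                  response_lag_s = 2)
  dev_hr <- synth_device_hr(traj, dev_model, seed = seeds[["dev"]])
  drop_iv <- data.frame(start_s = p$dropout_start_s,
                        end_s = p$dropout_start_s + p$dropout_len_s)
  sc <- split_streamed_cached(ecg$stream, drop_iv, p$clock_offset_s)
  write_stream_csv(sc$streamed, out("ecg_streamed.csv"))
  write_stream_csv(dev_hr, out("device_hr.csv"))
  stages$simulate <- list(n_beats = length(ecg$beat_times_s),
                          n_ecg_samples = stream_length(ecg$stream))

  # --- fuse -----------------------------------------------------------
  tab <- synchronize(list(sc$streamed, dev_hr), sync_config(200), events = tl)
  write_session(tab, out("session.json"))
  stages$fuse <- list(n_ticks = length(tab$tick_times_ns),
                      columns = names(tab$columns))

  # --- align ----------------------------------------------------------
  lag <- estimate_lag_xcorr(sc$streamed, sc$cached, max_lag_s = 10,
                            fs_hz = 200, segment = c(0, 120))
  map <- fit_clock_map(lag)
  patched <- patch_gaps(sc$streamed, sc$cached, map)
  write_stream_csv(patched, out("ecg_patched.csv"))
  stages$align <- list(lag_s = lag$lag_s, peak_corr = lag$peak_corr,
                       injected_offset_s = p$clock_offset_s,
                       n_cached_used = sum(patched$provenance == "cached"))

  # --- hr -------------------------------------------------------------
  beats <- detect_rpeaks(patched, fs_hz = 200)
  hr <- smooth_hr(beats, 100)
  write_stream_csv(hr, out("hr_smoothed.csv"))
  qr <- rpeak_quality(beats, tl, truth_beat_times_s = ecg$beat_times_s)
  write_report(list(quality = qr), out("hr_quality.json"), cfg)
  stages$hr <- list(n_beats = length(beats$rpeak_times_s))

  # --- agree ----------------------------------------------------------
  pairs <- crop_and_resample(hr, dev_hr, tl, rate_hz = 10)
  pe <- pearson_agreement(pairs)
  ba <- bland_altman(pairs)
  write_report(list(pearson = pe,
                    bland_altman = ba[c("n", "bias", "sd_diff", "loa_low",
                                        "loa_high", "prop_bias_slope")]),
               out("agreement.json"), cfg)
  stages$agree <- list(r = pe$r, bias = ba$bias)

  # --- sto2-qc --------------------------------------------------------
  otl <- make_timeline(protocol_template("occlusion"))
  sto2 <- synth_sto2_occlusion(otl, noise_sd = 0.8, seed = seeds[["sto2"]])
  fl <- plausibility_filter(sto2)
  norm <- normalize_occlusion(sto2, otl)
  write_report(list(rejection = fl$report[c("n_total", "n_rejected",
                                            "rejection_rate_pct",
                                            "reason_counts")],
                    frames_per_phase = vapply(norm$values, length,
                                              integer(1))),
               out("sto2_qc.json"), cfg)
  stages$sto2_qc <- list(rejection_rate_pct = fl$report$rejection_rate_pct)

  # --- eeg ------------------------------------------------------------
  if (cfg$include_eeg) {
    sim <- synth_eeg_simon(n_blocks = cfg$eeg_blocks, seed = seeds[["eeg"]])
    rec <- eeg_preprocess(sim$rec)
    blinks <- detect_blinks(rec)
    cl <- blink_ica_clean(rec, blinks)
    trials <- classify_trials(sim$trials)
    es <- epoch_and_reject(cl$rec, trial_meta = trials)
    es <- channel_hygiene(es)
    # time-frequency on response-locked epochs of included trials plus
    # their stimulus-locked partners (bounded for runtime)
    inc <- trials$trial[trials$included]
    sel <- which(es$meta$trial %in% inc & !es$rejected)
    sel <- sel[es$meta$trial[sel] %in%
                 intersect(es$meta$trial[sel][es$meta$label[sel] == "stimulus"],
                           es$meta$trial[sel][es$meta$label[sel] == "response"])]
    err_tr <- unique(es$meta$trial[sel][es$meta$accuracy[sel] %in% "error"])
    cor_tr <- setdiff(unique(es$meta$trial[sel]), err_tr)
    use_tr <- c(err_tr, utils::head(cor_tr, max(20, length(err_tr))))
    sel <- sel[es$meta$trial[sel] %in% use_tr]
    tf <- morlet_tf(es, keep_epochs = sel, decim = 8)
    tfn <- baseline_normalize(tf)
    avg <- tf_condition_average(tfn, lock = "response", by = "accuracy")
    roi_f <- tfn$freqs >= 4 & tfn$freqs <= 7
    roi_t <- tfn$times_ms >= 0 & tfn$times_ms <= 400
    roi_ch <- match(c("Fz", "Cz"), tfn$channel_labels)
    theta <- vapply(avg, function(a) mean(a[roi_ch, roi_f, roi_t]),
                    numeric(1))
    eeg_qc <- list(n_blinks_detected = length(blinks),
                   blink_component = cl$blink_component,
                   n_epochs = nrow(es$meta),
                   n_epochs_rejected = sum(es$rejected),
                   channels_interpolated = es$interpolated_channels,
                   participant_excluded = es$participant_excluded,
                   trial_status_counts = as.list(table(trials$status)),
                   theta_db = as.list(theta))
    write_report(eeg_qc, out("eeg_qc.json"), cfg)
    stages$eeg <- list(theta_contrast_db =
                         unname(theta["error"] - theta["correct"]))
  }

  # --- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(cfg$out_dir, files))
  manifest <- list(config = cfg[c("seed", "protocol", "include_eeg",
                                  "eeg_blocks", "params")],
                   package_version =
                     as.character(utils::packageVersion("physiofuse")),
                   stages = stages,
                   files = data.frame(name = files, md5 = unname(sums)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
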