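#' Crop two streams to the experiment timeline and co-resample to a shared
#' grid
#'
#' Both series are linearly interpolated onto one shared grid (default
#' 10 Hz) spanning the event timeline; the grid includes the start tick and
#' excludes the end (so a 60 s timeline at 10 Hz yields 600 pairs). Grid
#' points where either side has no coverage are dropped pairwise.
#'
#' @param a,b `ts_stream`s with overlapping coverage of the timeline.
#' @param timeline an `event_timeline`.
#' @param rate_hz shared grid rate (default 10 Hz).
#' @return data.frame with `t_s` (relative to timeline start), `a`, `b`.
#' @export
crop_and_resample <- function(a, b, timeline, rate_hz = 10) {
  t0 <- min(timeline$start_ns) / 1e9
  t1 <- max(timeline$end_ns) / 1e9
  grid <- seq(t0, t1 - 1 / rate_hz + 1e-12, by = 1 / rate_hz)
  va <- stream_approx(a, grid)
  vb <- stream_approx(b, grid)
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) stop("no overlapping coverage between streams on the timeline")
  data.frame(t_s = grid[ok] - t0, a = va[ok], b = vb[ok])
}

#' Normalize a stream onto a per-phase progress axis
#'
#' Within each protocol phase the series is interpolated at `n_points`
#' equally spaced progress fractions from 0 to 1 (endpoints preserved
#' exactly), so sessions with different phase durations share one shape and
#' can be averaged element-wise.
#'
#' @param stream a `ts_stream`.
#' @param timeline an `event_timeline`.
#' @param n_points samples per phase (default 500).
#' @param method `"linear"` (default) or `"cubic"` (natural cubic spline).
#' @param subject_id,device_id labels carried on the result.
#' @return class `phase_normalized`: list with `phase_labels`,
#'   `progress` (shared grid in [0,1]), `values` (named list, one numeric
#'   vector of length `n_points` per phase), `subject_id`, `device_id`.
#' @export
normalize_phase_progress <- function(stream, timeline, n_points = 500,
                                     method = c("linear", "cubic"),
                                     subject_id = "s1",
                                     device_id = stream$device_id) {
  method <- match.arg(method)
  ts <- stream$timestamps_ns[stream$valid] / 1e9
  v <- stream$values[stream$valid]
  grid01 <- seq(0, 1, length.out = n_points)
  vals <- list()
  for (i in seq_len(nrow(timeline))) {
    p0 <- timeline$start_ns[i] / 1e9
    p1 <- timeline$end_ns[i] / 1e9
    tt <- p0 + grid01 * (p1 - p0)
    vals[[timeline$label[i]]] <- if (method == "linear")
      stats::approx(ts, v, xout = tt, rule = 2)$y
    else stats::spline(ts, v, xout = tt, method = "natural")$y
  }
  structure(list(phase_labels = timeline$label, progress = grid01,
                 values = vals, subject_id = subject_id,
                 device_id = device_id),
            class = "phase_normalized")
}

#' Normalize an occlusion-protocol trace at a fixed frame rate per nominal
#' minute, with cubic interpolation
#'
#' Each phase is resampled to `frames_per_min` times the phase's nominal
#' duration in minutes (3-min baseline -> 3,000 frames; 1-min cuff steps ->
#' 1,000 each; 5-min recovery -> 5,000; 11,000 frames in total for the
#' standard ramp), using cubic-spline interpolation by default.
#'
#' @param stream a `ts_stream` (typically StO2).
#' @param timeline the occlusion `event_timeline`.
#' @param frames_per_min frames per nominal minute (default 1000).
#' @param method `"cubic"` (default) or `"linear"`.
#' @inheritParams normalize_phase_progress
#' @return a `phase_normalized` object whose per-phase lengths differ
#'   (`progress` is `NULL`; each `values[[phase]]` has its own length).
#' @export
normalize_occlusion <- function(stream, timeline, frames_per_min = 1000,
                                method = c("cubic", "linear"),
                                subject_id = "s1",
                                device_id = stream$device_id) {
  method <- match.arg(method)
  ts <- stream$timestamps_ns[stream$valid] / 1e9
  v <- stream$values[stream$valid]
  vals <- list()
  for (i in seq_len(nrow(timeline))) {
    p0 <- timeline$start_ns[i] / 1e9
    p1 <- timeline$end_ns[i] / 1e9
    n_i <- round(frames_per_min * (p1 - p0) / 60)
    tt <- seq(p0, p1, length.out = n_i)
    vals[[timeline$label[i]]] <- if (method == "cubic")
      stats::spline(ts, v, xout = tt, method = "natural")$y
    else stats::approx(ts, v, xout = tt, rule = 2)$y
  }
  structure(list(phase_labels = timeline$label, progress = NULL,
                 values = vals, subject_id = subject_id,
                 device_id = device_id),
            class = "phase_normalized")
}

#' Pearson agreement between paired device series
#'
#' @param pairs data.frame with columns `a`, `b` (from
#'   [crop_and_resample()]), or two numeric vectors via `b`.
#' @param b optional second vector when `pairs` is a numeric vector.
#' @return list with `r`, `p` (two-sided), `n`.
#' @export
pearson_agreement <- function(pairs, b = NULL) {
  if (!is.null(b)) pairs <- data.frame(a = pairs, b = b)
  ct <- stats::cor.test(pairs$a, pairs$b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
}

#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean difference `a - b`), the SD of the differences,
#' limits of agreement at bias ± 1.96 SD, and the proportional-bias slope
#' from an ordinary least-squares regression of the differences on the pair
#' means `(a + b) / 2`. The per-pair differences and means are returned for
#' plotting.
#'
#' @inheritParams pearson_agreement
#' @return class `agreement_result`: list with `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `prop_bias_slope`, and the plot payload
#'   `differences`, `means`.
#' @export
bland_altman <- function(pairs, b = NULL) {
  if (!is.null(b)) pairs <- data.frame(a = pairs, b = b)
  if (nrow(pairs) < 3) stop("Bland-Altman needs at least 3 pairs")
  d <- pairs$a - pairs$b
  m <- (pairs$a + pairs$b) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  slope <- if (stats::sd(m) == 0) 0
  else unname(stats::coef(stats::lm(d ~ m))[2])
  structure(list(n = length(d), bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 prop_bias_slope = slope, differences = d, means = m),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(paste0("<agreement_result> n=%d  bias %.3f  SD %.3f  ",
                     "LOA [%.3f, %.3f]  slope %.4f\n"),
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high,
              x$prop_bias_slope))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' Differences against pair means with bias and limit-of-agreement lines.
#'
#' @param x an `agreement_result`.
#' @param ... passed to [plot()].
#' @export
plot.agreement_result <- function(x, ...) {
  plot(x$means, x$differences, xlab = "Pair mean", ylab = "Difference (a - b)",
       main = "Bland-Altman", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("blue", "red", "red"))
  invisible(x)
}

#' Element-wise group mean ± SEM across phase-normalized subjects
#'
#' All inputs must share the same phase labels and per-phase lengths. SEM
#' uses the n−1 SD; elements with a single contributing subject get
#' `NA` SEM.
#'
#' @param series list of `phase_normalized` objects.
#' @return list with `phase_labels`, per-phase `mean`, `sem`, `n` lists.
#' @export
group_mean_sem <- function(series) {
  stopifnot(length(series) >= 1)
  labs <- series[[1]]$phase_labels
  out_mean <- list(); out_sem <- list(); out_n <- list()
  for (ph in labs) {
    mat <- vapply(series, function(s) s$values[[ph]],
                  numeric(length(series[[1]]$values[[ph]])))
    mat <- matrix(mat, ncol = length(series))
    n <- rowSums(!is.na(mat))
    mu <- rowMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 1, stats::sd, na.rm = TRUE)
    sem <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
    out_mean[[ph]] <- mu; out_sem[[ph]] <- sem; out_n[[ph]] <- n
  }
  list(phase_labels = labs, mean = out_mean, sem = out_sem, n = out_n)
}
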