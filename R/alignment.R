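#' Estimate the clock lag between a reference and a cached stream by
#' normalized cross-correlation
#'
#' Both streams are linearly resampled onto a common grid at `fs_hz`,
#' mean-removed, and cross-correlated (FFT-based) over lags within
#' `±max_lag_s`. The returned lag is the amount by which the cached copy's
#' clock leads the reference: subtracting it from the cached timestamps
#' aligns the two. Correlation is normalized (Pearson-type), so amplitude
#' scaling between the copies is irrelevant; a parabolic fit around the
#' integer-lag peak refines the estimate below the grid resolution.
#'
#' @param ref,cached `ts_stream`s with overlapping signal content.
#' @param max_lag_s lag search half-window in seconds.
#' @param fs_hz internal resampling rate (default 200 Hz).
#' @param segment optional `c(start_s, end_s)` restricting the reference
#'   window used (e.g. a pre-baseline segment of stable transmission),
#'   relative to the reference stream's first sample.
#' @return class `lag_estimate`: list with `lag_s`, `peak_corr`,
#'   `search_window_s`, `segment_used_ns`.
#' @export
estimate_lag_xcorr <- function(ref, cached, max_lag_s = 10, fs_hz = 200,
                               segment = NULL) {
  validate_ts_stream(ref); validate_ts_stream(cached)
  r0 <- ref$timestamps_ns[1] / 1e9
  r1 <- ref$timestamps_ns[stream_length(ref)] / 1e9
  if (!is.null(segment)) {
    r1 <- min(r1, r0 + segment[2]); r0 <- r0 + segment[1]
  }
  if ((r1 - r0) < 2 * max_lag_s)
    stop("insufficient overlap: reference window shorter than 2 x max_lag")
  tg <- seq(r0, r1, by = 1 / fs_hz)
  a <- stream_approx(ref, tg)
  # evaluate the cached stream on the same reference-time grid, extended by
  # the search window so shifted content is available
  ext <- seq(r0 - max_lag_s, r1 + max_lag_s, by = 1 / fs_hz)
  b <- stream_approx(cached, ext)
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  a <- a - mean(a); b <- b - mean(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: flat signal")
  max_k <- round(max_lag_s * fs_hz)
  # raw cross-correlation c[k] = sum_i a[i] * b[i + offset0 + k]
  nfft <- stats::nextn(length(ext) + length(a), 2)
  fa <- stats::fft(c(a, numeric(nfft - length(a))))
  fb <- stats::fft(c(b, numeric(nfft - length(b))))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / nfft
  # cc[m+1] corresponds to shifting b left by m relative to a; b's grid
  # starts max_k samples before a's, so shift m = max_k + k for lag k.
  ks <- (-max_k):max_k
  vals <- cc[max_k + ks + 1]
  i <- which.max(vals)
  k_hat <- ks[i]
  # sub-sample parabolic refinement
  frac <- 0
  if (i > 1 && i < length(vals)) {
    y1 <- vals[i - 1]; y2 <- vals[i]; y3 <- vals[i + 1]
    den <- (y1 - 2 * y2 + y3)
    if (den < 0) frac <- 0.5 * (y1 - y3) / den
  }
  lag_s <- (k_hat + frac) / fs_hz
  # peak correlation reported as the Pearson r at the integer-lag alignment
  bk <- b[(max_k + k_hat + 1):(max_k + k_hat + length(a))]
  peak_corr <- suppressWarnings(stats::cor(a, bk))
  structure(list(lag_s = lag_s, peak_corr = peak_corr,
                 search_window_s = max_lag_s,
                 segment_used_ns = round(c(r0, r1) * 1e9)),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> lag %.4f s (peak corr %.3f, window +/-%g s)\n",
              x$lag_s, x$peak_corr, x$search_window_s))
  invisible(x)
}

#' Fit an affine device-to-reference clock map
#'
#' With a single lag estimate the map is a pure offset (drift 0). With two
#' or more anchor pairs `(device_ts_ns, reference_ts_ns)` an offset plus
#' linear drift is fitted by least squares:
#' `device = reference * (1 + drift_ppm * 1e-6) + offset`.
#'
#' @param lag a `lag_estimate` (or a single numeric lag in seconds), or
#'   `NULL` if `pairs` is given.
#' @param pairs optional data.frame/matrix with columns `device_ns`,
#'   `reference_ns`.
#' @return class `clock_map`: list with `offset_s`, `drift_ppm`, and the
#'   internal affine coefficients.
#' @export
fit_clock_map <- function(lag = NULL, pairs = NULL) {
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    if (nrow(pairs) < 2) stop("need >= 2 anchor pairs to fit drift")
    # center to keep the regression well-conditioned with ns magnitudes
    rc <- mean(pairs$reference_ns)
    dc <- mean(pairs$device_ns)
    fit <- stats::lm((device_ns - dc) ~ I(reference_ns - rc), data = pairs)
    slope <- unname(stats::coef(fit)[2])
    intercept <- dc - slope * rc + unname(stats::coef(fit)[1])
    offset_s <- (intercept + (slope - 1) * rc) / 1e9   # offset at mid-session
    map <- list(offset_s = offset_s, drift_ppm = (slope - 1) * 1e6,
                slope = slope, intercept_ns = intercept)
  } else {
    if (inherits(lag, "lag_estimate")) lag <- lag$lag_s
    if (is.null(lag)) stop("clock map requires a lag estimate or anchor pairs")
    map <- list(offset_s = lag, drift_ppm = 0, slope = 1,
                intercept_ns = lag * 1e9)
  }
  structure(map, class = "clock_map")
}

#' Map device timestamps onto the reference clock (or back)
#'
#' Forward maps device-clock ns to reference-clock ns via the inverse of
#' `device = slope * reference + intercept`; `inverse = TRUE` applies the
#' device model itself. Round trip is identity to within 1 ns.
#'
#' @param map a `clock_map`.
#' @param ts_ns timestamps in ns.
#' @param inverse if `TRUE`, reference to device.
#' @export
apply_clock_map <- function(map, ts_ns, inverse = FALSE) {
  stopifnot(inherits(map, "clock_map"))
  if (inverse) map$slope * ts_ns + map$intercept_ns
  else (ts_ns - map$intercept_ns) / map$slope
}

#' Patch transmission gaps in a streamed recording from a cached copy
#'
#' Streamed samples are kept untouched everywhere they exist. A gap is an
#' inter-sample interval exceeding `gap_factor` times the nominal period;
#' inside each gap (and before the first / after the last streamed sample,
#' when the mapped cache extends further) the cached copy — re-timestamped
#' through the clock map — fills in. Duplicate timestamps resolve in favor
#' of streamed samples.
#'
#' @param streamed,cached `ts_stream`s (cached carries the device clock).
#' @param map a `clock_map` from [fit_clock_map()].
#' @param gap_factor gap threshold as a multiple of the nominal period
#'   (default 3).
#' @return a `ts_stream` with an extra `provenance` element
#'   (`"streamed"`/`"cached"` per sample).
#' @export
patch_gaps <- function(streamed, cached, map, gap_factor = 3) {
  if (missing(map) || is.null(map)) stop("clock map is required")
  validate_ts_stream(cached)
  rate <- streamed$native_rate_hz
  if (is.na(rate)) rate <- cached$native_rate_hz
  if (is.na(rate)) stop("nominal rate unknown; cannot define a gap")
  period_ns <- 1e9 / rate
  cts <- round(apply_clock_map(map, cached$timestamps_ns))
  st <- streamed$timestamps_ns
  n <- length(st)
  if (n == 0) {
    out <- cached
    out$timestamps_ns <- cts
    out$provenance <- rep("cached", length(cts))
    validate_ts_stream(out)
    return(out)
  }
  # candidate cached samples: inside internal gaps, or outside streamed span
  use <- rep(FALSE, length(cts))
  gaps <- which(diff(st) > gap_factor * period_ns)
  for (g in gaps)
    use <- use | (cts > st[g] & cts < st[g + 1])
  use <- use | cts < st[1] | cts > st[n]
  # drop cached samples effectively duplicating a streamed sample: within
  # half a nominal period of one (sub-sample clock-map error tolerance)
  pos <- findInterval(cts, st)
  d_lo <- ifelse(pos >= 1, cts - st[pmax(pos, 1)], Inf)
  d_hi <- ifelse(pos < n, st[pmin(pos + 1, n)] - cts, Inf)
  use <- use & pmin(d_lo, d_hi) >= period_ns / 2
  all_ts <- c(st, cts[use])
  all_v <- c(streamed$values, cached$values[use])
  all_valid <- c(streamed$valid, cached$valid[use])
  prov <- c(rep("streamed", n), rep("cached", sum(use)))
  o <- order(all_ts)
  keep <- !duplicated(all_ts[o])
  o <- o[keep]
  out <- streamed
  out$timestamps_ns <- all_ts[o]
  out$values <- all_v[o]
  out$valid <- all_valid[o]
  out$provenance <- prov[o]
  validate_ts_stream(out)
  out
}
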