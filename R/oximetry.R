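#' StO2 plausibility filter configuration
#'
#' @param low_pct reject below this saturation (default 5%).
#' @param high_pct reject above this (default 95%).
#' @param jump_pct reject if the absolute change from the last *accepted*
#'   sample exceeds this (default 20 percentage points).
#' @return class `sto2_filter_config`.
#' @export
sto2_filter_config <- function(low_pct = 5, high_pct = 95, jump_pct = 20) {
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop("need 0 <= low < high <= 100")
  if (jump_pct <= 0) stop("jump_pct must be > 0")
  structure(list(low_pct = low_pct, high_pct = high_pct,
                 jump_pct = jump_pct), class = "sto2_filter_config")
}

#' Physiological plausibility filter for StO2 traces
#'
#' A sample is rejected if its value is below `low_pct`, above `high_pct`,
#' or differs from the previous *accepted* sample by more than `jump_pct`
#' (the first sample is exempt from the jump rule). Comparing against the
#' last accepted sample — not the last raw sample — prevents one spike from
#' cascading rejections. Each rejected sample carries a single primary
#' reason with precedence low > high > jump.
#'
#' @param sto2 a `ts_stream` of StO2 in percent.
#' @param cfg an [sto2_filter_config()].
#' @return list with `mask` (logical, `TRUE` = accepted, aligned to the
#'   input) and `report` (class `rejection_report`: `n_total`,
#'   `n_rejected`, `rejection_rate_pct`, `reason_counts`).
#' @export
plausibility_filter <- function(sto2, cfg = sto2_filter_config()) {
  validate_ts_stream(sto2)
  v <- sto2$values
  n <- length(v)
  mask <- logical(n)
  reasons <- character(0)
  last_ok <- NA_real_
  for (i in seq_len(n)) {
    if (v[i] < cfg$low_pct) {
      reasons <- c(reasons, "low")
    } else if (v[i] > cfg$high_pct) {
      reasons <- c(reasons, "high")
    } else if (!is.na(last_ok) && abs(v[i] - last_ok) > cfg$jump_pct) {
      reasons <- c(reasons, "jump")
    } else {
      mask[i] <- TRUE
      last_ok <- v[i]
    }
  }
  rc <- c(low = sum(reasons == "low"), high = sum(reasons == "high"),
          jump = sum(reasons == "jump"))
  report <- structure(list(
    n_total = n, n_rejected = as.integer(n - sum(mask)),
    rejection_rate_pct = if (n > 0) 100 * (n - sum(mask)) / n else NA_real_,
    reason_counts = as.list(rc)), class = "rejection_report")
  list(mask = mask, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %d/%d rejected (%.1f%%): low %d, high %d, jump %d\n",
              x$n_rejected, x$n_total, x$rejection_rate_pct,
              x$reason_counts$low, x$reason_counts$high, x$reason_counts$jump))
  invisible(x)
}

#' Placement error rate of a test StO2 site against the reference site
#'
#' Per-tick signed percent difference `100 * (test - ref) / ref` over
#' mutually accepted, time-matched samples. Ticks where the reference is
#' zero are excluded and counted. Both a signed mean and a mean of absolute
#' percent differences are reported (the sign convention of an "error rate"
#' is ambiguous; both are useful).
#'
#' @param test,ref `ts_stream`s already filtered and synchronized to common
#'   ticks (timestamps are matched exactly).
#' @param test_mask,ref_mask optional acceptance masks from
#'   [plausibility_filter()] aligned to each stream.
#' @return list with `n_pairs`, `mean_error_pct` (signed),
#'   `mean_abs_error_pct`, `sd_error_pct`, `n_zero_ref_excluded`.
#' @export
placement_error_rate <- function(test, ref, test_mask = NULL, ref_mask = NULL) {
  validate_ts_stream(test); validate_ts_stream(ref)
  if (is.null(test_mask)) test_mask <- rep(TRUE, stream_length(test))
  if (is.null(ref_mask)) ref_mask <- rep(TRUE, stream_length(ref))
  ti <- test$timestamps_ns[test_mask]
  tv <- test$values[test_mask]
  ri <- ref$timestamps_ns[ref_mask]
  rv <- ref$values[ref_mask]
  common <- intersect(ti, ri)
  tv <- tv[match(common, ti)]
  rv <- rv[match(common, ri)]
  zero <- rv == 0
  err <- 100 * (tv[!zero] - rv[!zero]) / rv[!zero]
  list(n_pairs = length(err),
       mean_error_pct = if (length(err)) mean(err) else NA_real_,
       mean_abs_error_pct = if (length(err)) mean(abs(err)) else NA_real_,
       sd_error_pct = if (length(err) > 1) stats::sd(err) else NA_real_,
       n_zero_ref_excluded = sum(zero))
}

#' Summarize rejection and placement-error rates across sessions per
#' location
#'
#' Grand means across test cycles and subjects for each anatomical
#' position/orientation label; `n` reflects how many sessions actually
#' contributed each location.
#'
#' @param sessions list of per-session lists, each with elements `location`
#'   (label), `rejection_rate_pct`, and optionally `mean_abs_error_pct`.
#' @return data.frame with one row per location: `location`, `n`,
#'   `mean_rejection_rate_pct`, `mean_abs_error_pct`.
#' @export
location_summary <- function(sessions) {
  loc <- vapply(sessions, function(s) s$location, character(1))
  rej <- vapply(sessions, function(s) s$rejection_rate_pct, numeric(1))
  err <- vapply(sessions, function(s)
    if (is.null(s$mean_abs_error_pct)) NA_real_ else s$mean_abs_error_pct,
    numeric(1))
  out <- lapply(unique(loc), function(L) {
    i <- loc == L
    data.frame(location = L, n = sum(i),
               mean_rejection_rate_pct = mean(rej[i], na.rm = TRUE),
               mean_abs_error_pct = if (all(is.na(err[i]))) NA_real_
               else mean(err[i], na.rm = TRUE))
  })
  do.call(rbind, out)
}
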