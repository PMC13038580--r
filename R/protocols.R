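#' Protocol templates and event timelines
#'
#' A protocol template is an ordered list of labeled phases with durations
#' and per-phase parameters (a target heart-rate zone as a fraction of
#' HRmax, or a cuff pressure in mmHg). Two built-ins reproduce the standard
#' bench protocols:
#'
#' * `"occlusion"` — graded vaso-occlusive ramp: 3 min baseline (no
#'   occlusion), 1 min each at 100 / 150 / 200 mmHg, 5 min recovery.
#' * `"exercise"` — ramped recumbent-bike circuit: 2 min rest, 2 min each of
#'   mild (50--60% HRmax), moderate (60--70%), high (70--80%), 4 min
#'   recovery at rest.
#'
#' @param name `"occlusion"` or `"exercise"`, or supply `phases` directly.
#' @param phases optional data.frame with columns `label`, `duration_s`, and
#'   parameter columns (`pressure_mmhg`, `zone_lo`, `zone_hi`).
#' @return An object of class `protocol_template`.
#' @export
protocol_template <- function(name = c("occlusion", "exercise"), phases = NULL) {
  if (is.null(phases)) {
    name <- match.arg(name)
    phases <- switch(name,
      occlusion = data.frame(
        label = c("baseline", "occ_100", "occ_150", "occ_200", "recovery"),
        duration_s = c(180, 60, 60, 60, 300),
        pressure_mmhg = c(0, 100, 150, 200, 0),
        zone_lo = NA_real_, zone_hi = NA_real_),
      exercise = data.frame(
        label = c("rest", "mild", "moderate", "high", "recovery"),
        duration_s = c(120, 120, 120, 120, 240),
        pressure_mmhg = NA_real_,
        zone_lo = c(NA, 0.50, 0.60, 0.70, NA),
        zone_hi = c(NA, 0.60, 0.70, 0.80, NA)))
  } else {
    name <- if (is.character(name) && length(name) == 1) name[1] else "custom"
  }
  if (any(phases$duration_s <= 0))
    stop("invalid protocol template: phase durations must be > 0")
  if (anyDuplicated(phases$label))
    stop("invalid protocol template: phase labels must be unique")
  structure(list(name = name, phases = phases), class = "protocol_template")
}

#' @export
print.protocol_template <- function(x, ...) {
  cat(sprintf("<protocol_template> %s: %d phases, %.0f s total\n",
              x$name, nrow(x$phases), sum(x$phases$duration_s)))
  print(x$phases)
  invisible(x)
}

#' Expand a protocol template into a labeled event timeline
#'
#' Produces contiguous, non-overlapping labeled intervals covering the full
#' template duration, in epoch nanoseconds.
#'
#' @param template a [protocol_template()].
#' @param start_ns session start, epoch ns (default 0).
#' @return An `event_timeline`: data.frame with `label`, `start_ns`,
#'   `end_ns`, plus the template's phase parameter columns, wrapped with
#'   class `event_timeline`.
#' @export
make_timeline <- function(template, start_ns = 0) {
  stopifnot(inherits(template, "protocol_template"))
  ph <- template$phases
  if (any(ph$duration_s <= 0)) stop("invalid template: zero/negative duration")
  ends <- start_ns + cumsum(ph$duration_s) * 1e9
  starts <- c(start_ns, ends[-length(ends)])
  tl <- data.frame(label = ph$label, start_ns = starts, end_ns = ends)
  extra <- setdiff(names(ph), c("label", "duration_s"))
  for (col in extra) tl[[col]] <- ph[[col]]
  structure(tl, class = c("event_timeline", "data.frame"))
}

#' Total duration of a timeline in seconds
#' @param timeline an `event_timeline`.
#' @export
timeline_duration_s <- function(timeline) {
  (max(timeline$end_ns) - min(timeline$start_ns)) / 1e9
}

#' Label each time point with its protocol phase
#'
#' @param timeline an `event_timeline`.
#' @param t_ns numeric vector of epoch-ns times.
#' @return character vector of phase labels (`NA` outside the timeline).
#'   Intervals are closed on the left, open on the right; the final phase is
#'   closed on both sides so the session endpoint is labeled.
#' @export
phase_at <- function(timeline, t_ns) {
  lab <- rep(NA_character_, length(t_ns))
  n <- nrow(timeline)
  for (i in seq_len(n)) {
    inph <- t_ns >= timeline$start_ns[i] &
      (t_ns < timeline$end_ns[i] | (i == n & t_ns <= timeline$end_ns[i]))
    lab[inph] <- timeline$label[i]
  }
  lab
}
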