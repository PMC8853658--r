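# Domain containers for one recording session. Time is in seconds, float,
# session-relative (t = 0 at recording start); all windows are half-open
# [a, b). Pixel coordinates follow the image convention: origin top-left,
# y increasing downward.

POSE_PARTS <- c("nose", "left_ear", "right_ear", "head_center", "spine",
                "tail_base")
PHASES <- c("pre", "reward", "odor", "conflict", "post")
EVENT_LABELS <- c("food_cue", "lever_press", "dish_entry", "laser_pulse",
                  "behavior_onset")

#' Spike train of one sorted unit
#'
#' @param unit_id unit identifier.
#' @param spike_times strictly increasing spike times, seconds.
#' @param t_start,t_stop recording bounds, seconds.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(unit_id, spike_times, t_start, t_stop) {
  st <- structure(list(unit_id = as.character(unit_id),
                       spike_times = as.numeric(spike_times),
                       t_start = as.numeric(t_start),
                       t_stop = as.numeric(t_stop)),
                  class = "spike_train")
  v <- validate_spike_train(st)
  if (length(v)) stopf("invalid spike_train: %s", paste(v, collapse = "; "))
  st
}

validate_spike_train <- function(st) {
  out <- character()
  ts <- st$spike_times
  if (length(ts) && any(diff(ts) <= 0))
    out <- c(out, sprintf("unit %s: spike times not strictly increasing",
                          st$unit_id))
  if (length(ts) && (ts[1] < st$t_start || ts[length(ts)] > st$t_stop))
    out <- c(out, sprintf("unit %s: spike time outside [t_start, t_stop]",
                          st$unit_id))
  if (st$t_stop <= st$t_start)
    out <- c(out, sprintf("unit %s: t_stop <= t_start", st$unit_id))
  out
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- x$t_stop - x$t_start
  cat(sprintf("<spike_train %s> %d spikes over %.1f s (%.2f Hz)\n",
              x$unit_id, length(x$spike_times), dur,
              length(x$spike_times) / dur))
  invisible(x)
}

#' Labeled event series
#'
#' One series per event label; point events have zero duration. `rewarded`
#' is meaningful for cue and press events and NA otherwise. `train` optionally
#' groups laser pulses into stimulation trains.
#'
#' @param label one of `food_cue`, `lever_press`, `dish_entry`,
#'   `laser_pulse`, `behavior_onset`.
#' @param onsets ascending onset times, seconds.
#' @param durations event durations, seconds (recycled).
#' @param phase phase tag per event (recycled).
#' @param rewarded logical per event (recycled).
#' @param train optional integer train id per event.
#' @return object of class `event_series`.
#' @export
event_series <- function(label, onsets, durations = 0,
                         phase = "reward", rewarded = NA, train = NULL) {
  n <- length(onsets)
  es <- structure(list(label = match.arg(label, EVENT_LABELS),
                       onsets = as.numeric(onsets),
                       durations = rep_len(as.numeric(durations), n),
                       phase = rep_len(as.character(phase), n),
                       rewarded = rep_len(as.logical(rewarded), n),
                       train = if (!is.null(train))
                         rep_len(as.integer(train), n)),
                  class = "event_series")
  v <- validate_event_series(es)
  if (length(v)) stopf("invalid event_series: %s", paste(v, collapse = "; "))
  es
}

validate_event_series <- function(es) {
  out <- character()
  if (is.unsorted(es$onsets))
    out <- c(out, sprintf("events %s: onsets not sorted ascending", es$label))
  if (any(es$durations < 0))
    out <- c(out, sprintf("events %s: negative duration", es$label))
  if (!all(es$phase %in% PHASES))
    out <- c(out, sprintf("events %s: unknown phase tag", es$label))
  out
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series %s> %d events (%s)\n", x$label,
              length(x$onsets),
              paste(sprintf("%s: %d", names(table(x$phase)), table(x$phase)),
                    collapse = ", ")))
  invisible(x)
}

#' Pose track from a DeepLabCut-style analysis
#'
#' Per-frame pixel coordinates and likelihood for the six tracked body parts.
#' Masked frames carry NA coordinates (likelihood retained).
#'
#' @param frame_times frame timestamps, seconds.
#' @param frame_rate nominal frame rate, Hz.
#' @param x,y,likelihood numeric matrices, frames x parts, with the parts
#'   `nose`, `left_ear`, `right_ear`, `head_center`, `spine`, `tail_base`
#'   as column names.
#' @return object of class `pose_track`.
#' @export
pose_track <- function(frame_times, frame_rate, x, y, likelihood) {
  pt <- structure(list(frame_times = as.numeric(frame_times),
                       frame_rate = frame_rate,
                       x = as.matrix(x), y = as.matrix(y),
                       likelihood = as.matrix(likelihood)),
                  class = "pose_track")
  v <- validate_pose_track(pt)
  if (length(v)) stopf("invalid pose_track: %s", paste(v, collapse = "; "))
  pt
}

validate_pose_track <- function(pt) {
  out <- character()
  for (m in c("x", "y", "likelihood")) {
    cn <- colnames(pt[[m]])
    if (is.null(cn) || !setequal(cn, POSE_PARTS))
      out <- c(out, sprintf("pose %s matrix must have columns {%s}", m,
                            paste(POSE_PARTS, collapse = ", ")))
    if (nrow(pt[[m]]) != length(pt$frame_times))
      out <- c(out, sprintf("pose %s matrix rows != n frames", m))
  }
  if (length(pt$frame_times) > 1) {
    dt <- diff(pt$frame_times)
    if (any(abs(dt - 1 / pt$frame_rate) > 0.01 / pt$frame_rate))
      out <- c(out, "pose frame_times not uniform to within 1% of 1/frame_rate")
  }
  lk <- pt$likelihood
  if (any(lk < 0 | lk > 1, na.rm = TRUE))
    out <- c(out, "pose likelihood outside [0, 1]")
  out
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames at %g Hz, %d parts, %.1f%% masked\n",
              length(x$frame_times), x$frame_rate, ncol(x$x),
              100 * mean(is.na(x$x))))
  invisible(x)
}

#' Arena zone geometry
#'
#' Axis-aligned zone rectangles (closed) in pixel coordinates and the slot
#' segment: the opening in the divider between the hidden and open areas.
#'
#' @param zones named list of c(xmin, xmax, ymin, ymax) rectangles; must
#'   contain `hidden`, `center` and `food`.
#' @param slot 2x2 matrix, rows are the segment endpoints (x, y).
#' @return object of class `arena_layout`.
#' @export
arena_layout <- function(zones, slot) {
  al <- structure(list(zones = lapply(zones, as.numeric),
                       slot = matrix(as.numeric(slot), 2, 2)),
                  class = "arena_layout")
  v <- validate_arena_layout(al)
  if (length(v)) stopf("invalid arena_layout: %s", paste(v, collapse = "; "))
  al
}

validate_arena_layout <- function(al) {
  out <- character()
  need <- c("hidden", "center", "food")
  if (!all(need %in% names(al$zones)))
    out <- c(out, "arena zones must include hidden, center, food")
  for (nm in names(al$zones)) {
    z <- al$zones[[nm]]
    if (length(z) != 4 || z[2] <= z[1] || z[4] <= z[3])
      out <- c(out, sprintf("zone %s: malformed rectangle", nm))
  }
  zs <- al$zones[names(al$zones) %in% need]
  if (length(zs) == 3 && !length(out)) {
    for (i in 1:2) for (j in (i + 1):3) {
      a <- zs[[i]]; b <- zs[[j]]
      if (a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4])
        out <- c(out, sprintf("zones %s and %s overlap", names(zs)[i],
                              names(zs)[j]))
    }
  }
  out
}

#' Continuous field-potential signal
#'
#' @param samples voltage samples, microvolts.
#' @param fs sampling rate, Hz (must exceed twice the highest analyzed
#'   frequency; >= 200 Hz for the 0-100 Hz analysis).
#' @param t_start time of the first sample, seconds.
#' @return object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs, t_start = 0) {
  sig <- structure(list(samples = as.numeric(samples), fs = fs,
                        t_start = t_start),
                   class = "lfp_signal")
  v <- validate_lfp_signal(sig)
  if (length(v)) stopf("invalid lfp_signal: %s", paste(v, collapse = "; "))
  sig
}

validate_lfp_signal <- function(sig) {
  if (sig$fs < 200) "lfp sampling rate below 200 Hz (0-100 Hz analysis)"
  else character()
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> %.1f s at %g Hz\n",
              length(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Recording session container
#'
#' @param subject_id subject identifier.
#' @param phase_intervals named list phase -> c(start, end), seconds; the
#'   behavioral phases must be ordered reward < odor < conflict and must not
#'   overlap.
#' @param units list of [spike_train] objects.
#' @param events list of [event_series] objects.
#' @param phenotype `presser`, `non_presser` or `unknown`.
#' @param pose optional [pose_track].
#' @param lfp optional [lfp_signal].
#' @param arena optional [arena_layout].
#' @param t_start,t_stop recording bounds; defaults from units.
#' @return object of class `session`.
#' @export
session <- function(subject_id, phase_intervals, units = list(),
                    events = list(), phenotype = "unknown", pose = NULL,
                    lfp = NULL, arena = NULL, t_start = NULL, t_stop = NULL) {
  if (is.null(t_start))
    t_start <- if (length(units)) min(sapply(units, `[[`, "t_start")) else 0
  if (is.null(t_stop))
    t_stop <- if (length(units)) max(sapply(units, `[[`, "t_stop")) else
      max(unlist(lapply(phase_intervals, `[`, 2)))
  s <- structure(list(subject_id = as.character(subject_id),
                      phenotype = match.arg(phenotype,
                                            c("unknown", "presser",
                                              "non_presser")),
                      phase_intervals = lapply(phase_intervals, as.numeric),
                      units = units, events = events, pose = pose, lfp = lfp,
                      arena = arena, t_start = t_start, t_stop = t_stop),
                 class = "session")
  v <- validate_session(s)
  if (length(v)) stopf("invalid session: %s", paste(v, collapse = "; "))
  s
}

#' Report every invariant violation in a session
#'
#' Pure reporting: returns a character vector of human-readable violations,
#' empty when the session is valid. Used by [session()] and [load_session()]
#' to fail fast, and directly useful for fuzzing tests.
#'
#' @param s a `session` (or a bare list with the same fields).
#' @return character vector of violation descriptions.
#' @export
validate_session <- function(s) {
  out <- character()
  pi <- s$phase_intervals
  if (!all(names(pi) %in% PHASES))
    out <- c(out, "phase_intervals: unknown phase name")
  for (nm in names(pi)) {
    iv <- pi[[nm]]
    if (length(iv) != 2 || iv[2] <= iv[1])
      out <- c(out, sprintf("phase_intervals: %s malformed", nm))
  }
  main <- intersect(c("reward", "odor", "conflict"), names(pi))
  if (length(main) > 1) {
    ivs <- pi[main]
    st <- sapply(ivs, `[`, 1); en <- sapply(ivs, `[`, 2)
    ord <- c(reward = 1, odor = 2, conflict = 3)[main]
    if (any(diff(st[order(ord)]) <= 0))
      out <- c(out, "phase_intervals: phases not ordered reward < odor < conflict")
    o <- order(st)
    if (any(st[o][-1] < en[o][-length(en)]))
      out <- c(out, "phase_intervals: overlapping phase intervals")
  }
  for (u in s$units) out <- c(out, validate_spike_train(u))
  for (es in s$events) {
    out <- c(out, validate_event_series(es))
    bad <- es$onsets < s$t_start | es$onsets > s$t_stop
    if (any(bad))
      out <- c(out, sprintf("events %s: onset %.3f s outside recording bounds",
                            es$label, es$onsets[which(bad)[1]]))
  }
  if (!is.null(s$pose)) out <- c(out, validate_pose_track(s$pose))
  if (!is.null(s$lfp)) out <- c(out, validate_lfp_signal(s$lfp))
  if (!is.null(s$arena)) out <- c(out, validate_arena_layout(s$arena))
  out
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session %s> phenotype %s, %d units, %d event series\n",
              x$subject_id, x$phenotype, length(x$units), length(x$events)))
  cat(sprintf("  phases: %s\n",
              paste(sprintf("%s [%.0f, %.0f)", names(x$phase_intervals),
                            sapply(x$phase_intervals, `[`, 1),
                            sapply(x$phase_intervals, `[`, 2)),
                    collapse = ", ")))
  cat(sprintf("  pose: %s, lfp: %s, arena: %s\n",
              if (is.null(x$pose)) "no" else "yes",
              if (is.null(x$lfp)) "no" else "yes",
              if (is.null(x$arena)) "no" else "yes"))
  invisible(x)
}

# Fetch the single event series with a given label (or NULL).
session_events <- function(s, label) {
  for (es in s$events) if (es$label == label) return(es)
  NULL
}
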