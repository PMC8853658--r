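# Pose-track behavior detection. A frame is "still" if every tracked part
# moved at most freeze_tol pixels since the previous frame; zone membership
# uses closed rectangles; the divider line is the hidden-zone boundary facing
# the open area.

# Interpolate masked (NA) coordinates across gaps <= pose_gap_max; longer
# gaps stay NA and are excluded from bout detection.
pose_clean <- function(pose, config = analysis_config()) {
  max_gap <- round(config$pose_gap_max * pose$frame_rate)
  fill <- function(v) {
    if (!anyNA(v) || all(is.na(v))) return(v)
    na <- is.na(v)
    runs <- true_runs(na)
    ok <- runs$end - runs$start + 1 <= max_gap &
      runs$start > 1 & runs$end < length(v)
    out <- v
    idx <- unlist(mapply(seq, runs$start[ok], runs$end[ok],
                         SIMPLIFY = FALSE))
    if (length(idx))
      out[idx] <- stats::approx(which(!na), v[!na], xout = idx)$y
    out
  }
  x <- apply(pose$x, 2, fill)
  y <- apply(pose$y, 2, fill)
  valid <- !apply(is.na(x) | is.na(y), 1, any)
  list(x = x, y = y, valid = valid,
       t = pose$frame_times, dt = 1 / pose$frame_rate)
}

bouts_df <- function(type, onset, duration) {
  data.frame(type = as.character(type), onset_s = as.numeric(onset),
             duration_s = as.numeric(duration))
}

# Maximal runs of a per-frame predicate -> bouts (duration = n frames * dt).
frames_to_bouts <- function(flag, t, dt, type) {
  flag[is.na(flag)] <- FALSE
  runs <- true_runs(flag)
  if (!nrow(runs)) return(bouts_df(character(), numeric(), numeric()))
  bouts_df(type, t[runs$start], (runs$end - runs$start + 1) * dt)
}

point_in_rect <- function(x, y, r) x >= r[1] & x <= r[2] & y >= r[3] & y <= r[4]

#' Detect freezing bouts
#'
#' A frame is still if every tracked part's displacement from the previous
#' frame is at most `freeze_tol` pixels (1.05 by default); maximal still runs
#' lasting strictly more than `freeze_min_dur` (500 ms) become bouts. A run
#' of k still frame-to-frame transitions spans k/frame_rate seconds starting
#' at the frame before the first still transition.
#'
#' @param pose a [pose_track].
#' @param config an [analysis_config].
#' @return data.frame of bouts: `type`, `onset_s`, `duration_s`.
#' @export
detect_freezing <- function(pose, config = analysis_config()) {
  pc <- pose_clean(pose, config)
  n <- length(pc$t)
  if (n < 2) return(bouts_df(character(), numeric(), numeric()))
  disp <- sqrt(diff(pc$x)^2 + diff(pc$y)^2) # (n-1) x parts
  still <- apply(disp <= config$freeze_tol, 1, all) &
    pc$valid[-1] & pc$valid[-n]
  still[is.na(still)] <- FALSE
  runs <- true_runs(still)
  if (!nrow(runs)) return(bouts_df(character(), numeric(), numeric()))
  dur <- (runs$end - runs$start + 1) * pc$dt
  keep <- dur > config$freeze_min_dur
  bouts_df(rep("freezing", sum(keep)), pc$t[runs$start[keep]], dur[keep])
}

#' Detect avoidance bouts
#'
#' Maximal runs of frames with the head center inside the hidden zone
#' (closed rectangle).
#'
#' @param pose a [pose_track].
#' @param arena an [arena_layout].
#' @param config an [analysis_config].
#' @return data.frame of bouts.
#' @export
detect_avoidance <- function(pose, arena, config = analysis_config()) {
  pc <- pose_clean(pose, config)
  hz <- arena$zones$hidden
  inside <- point_in_rect(pc$x[, "head_center"], pc$y[, "head_center"], hz) &
    pc$valid
  frames_to_bouts(inside, pc$t, pc$dt, "avoidance")
}

#' Detect risk-assessment (stretch-attend) bouts
#'
#' A frame qualifies when the hindquarters are hidden (spine and tail base in
#' the hidden zone), the nose has crossed the divider toward the open area
#' within the slot's lateral extent, and the body is stretched: nose-to-tail
#' length at least the session mean plus `stretch_z` SDs.
#'
#' @param pose a [pose_track].
#' @param arena an [arena_layout] with a slot segment.
#' @param stretch_z body-length threshold in session SDs (default from
#'   `config`).
#' @param config an [analysis_config].
#' @return data.frame of bouts.
#' @export
detect_risk_assessment <- function(pose, arena, stretch_z = NULL,
                                   config = analysis_config()) {
  if (is.null(stretch_z)) stretch_z <- config$stretch_z
  pc <- pose_clean(pose, config)
  hz <- arena$zones$hidden
  # divider faces the open area; sign tells which side is "open"
  div_x <- arena$slot[1, 1]
  open_right <- mean(arena$zones$center[1:2]) > div_x
  slot_y <- sort(arena$slot[, 2])
  len <- sqrt((pc$x[, "nose"] - pc$x[, "tail_base"])^2 +
              (pc$y[, "nose"] - pc$y[, "tail_base"])^2)
  thr <- mean(len[pc$valid]) + stretch_z * stats::sd(len[pc$valid])
  beyond <- if (open_right) pc$x[, "nose"] > div_x else
    pc$x[, "nose"] < div_x
  qual <- point_in_rect(pc$x[, "spine"], pc$y[, "spine"], hz) &
    point_in_rect(pc$x[, "tail_base"], pc$y[, "tail_base"], hz) &
    beyond & pc$y[, "nose"] >= slot_y[1] & pc$y[, "nose"] <= slot_y[2] &
    len >= thr & pc$valid
  frames_to_bouts(qual, pc$t, pc$dt, "risk_assessment")
}

#' Filter behavior onsets for neural alignment
#'
#' Keeps the onset of each bout that lasted strictly more than `bout_min_dur`
#' (1 s) and was not preceded by a same-type bout intersecting the
#' `bout_refractory` (6 s) window before its onset, so the pre-onset baseline
#' is uncontaminated. The result is a subset of the input onsets and the
#' operation is idempotent.
#'
#' @param bouts data.frame of bouts (`type`, `onset_s`, `duration_s`).
#' @param config an [analysis_config].
#' @return data.frame with `type` and `onset_s` of the retained bouts.
#' @export
filter_onsets <- function(bouts, config = analysis_config()) {
  if (!nrow(bouts)) return(data.frame(type = character(), onset_s = numeric()))
  bouts <- bouts[order(bouts$onset_s), ]
  keep <- logical(nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    if (bouts$duration_s[i] <= config$bout_min_dur) next
    t0 <- bouts$onset_s[i]
    same <- bouts$type == bouts$type[i] & seq_len(nrow(bouts)) != i
    prior <- same & bouts$onset_s < t0 &
      bouts$onset_s + bouts$duration_s > t0 - config$bout_refractory
    keep[i] <- !any(prior)
  }
  bouts[keep, c("type", "onset_s")]
}

#' Classify a unit's response around behavior onsets
#'
#' Builds a fine-binned (100 ms) Z-scored histogram around the onsets, with a
#' 6-s baseline ending 600 ms before onset, and looks for threshold crossings
#' (`z_excite` / `z_inhibit`) within the 600-ms interval after onset
#' (`responds_after`) or before it (`responds_before`; the post-onset window
#' takes precedence when both cross). Units with fewer than six usable onsets
#' are excluded.
#'
#' @param unit a [spike_train].
#' @param onsets behavior onset times, seconds.
#' @param config an [analysis_config].
#' @return object of class `behavior_alignment`: `classification`
#'   (`responds_before`, `responds_after`, `none` or `excluded`), `direction`
#'   (`excited`/`inhibited`/NA), `z` and `bin_edges`, `n_onsets`.
#' @export
align_responses_to_behavior <- function(unit, onsets,
                                        config = analysis_config()) {
  aw <- config$behavior_align_window
  bl <- config$behavior_baseline
  bw <- config$behavior_align_bin
  usable <- onsets[onsets - (bl + aw) >= unit$t_start &
                   onsets + aw <= unit$t_stop]
  out <- list(unit_id = unit$unit_id, n_onsets = length(usable))
  if (length(usable) < config$min_behavior_onsets) {
    warning(sprintf("unit %s excluded: %d usable onsets (need %d)",
                    unit$unit_id, length(usable),
                    config$min_behavior_onsets))
    out$classification <- "excluded"
    out$direction <- NA_character_
    return(structure(out, class = "behavior_alignment"))
  }
  edges <- seq(-(bl + aw), aw, by = bw)
  mc <- mean_counts_by_bin(unit$spike_times, usable, edges)
  nb <- round(bl / bw)
  bm <- mean(mc[seq_len(nb)])
  bs <- sd_pop(mc[seq_len(nb)])
  zi <- (nb + 1):(length(mc))
  z <- if (bs > 0) (mc[zi] - bm) / bs else
    ifelse(mc[zi] == bm, 0, sign(mc[zi] - bm) * Inf)
  lefts <- edges[zi]
  cross <- z > config$z_excite | z < config$z_inhibit
  after <- lefts >= 0
  cls <- if (any(cross & after)) "responds_after"
  else if (any(cross & !after)) "responds_before"
  else "none"
  dir <- NA_character_
  if (cls != "none") {
    first <- which(cross & (after == (cls == "responds_after")))[1]
    dir <- if (z[first] > 0) "excited" else "inhibited"
  }
  out$classification <- cls
  out$direction <- dir
  out$z <- z
  out$bin_edges <- c(lefts, aw)
  structure(out, class = "behavior_alignment")
}

#' Classify a subject's conflict phenotype
#'
#' Presser if the subject made at least one rewarded lever press during a
#' conflict-phase food-cue presentation; non-presser otherwise (complete
#' suppression of pressing under conflict).
#'
#' @param s a [session] with a conflict phase.
#' @return `"presser"` or `"non_presser"`.
#' @export
classify_phenotype <- function(s) {
  if (!"conflict" %in% names(s$phase_intervals))
    stopf("session %s has no conflict phase", s$subject_id)
  presses <- session_events(s, "lever_press")
  if (is.null(presses)) return("non_presser")
  sel <- presses$phase == "conflict" & presses$rewarded %in% TRUE
  cues <- session_events(s, "food_cue")
  if (!is.null(cues)) {
    during_cue <- vapply(presses$onsets, function(t)
      any(t >= cues$onsets & t < cues$onsets + cues$durations), TRUE)
    sel <- sel & during_cue
  }
  if (any(sel)) "presser" else "non_presser"
}

#' Fraction of a window covered by bouts
#'
#' @param bouts data.frame of bouts.
#' @param window c(start, end), seconds.
#' @return fraction in [0, 1].
#' @export
bout_time_fraction <- function(bouts, window) {
  if (!nrow(bouts)) return(0)
  lo <- pmax(bouts$onset_s, window[1])
  hi <- pmin(bouts$onset_s + bouts$duration_s, window[2])
  sum(pmax(hi - lo, 0)) / diff(window)
}

#' Fraction of frames with the head center inside a zone
#'
#' @param pose a [pose_track].
#' @param arena an [arena_layout].
#' @param zone zone name.
#' @param window optional c(start, end) restriction, seconds.
#' @param config an [analysis_config].
#' @return fraction of valid frames inside the zone.
#' @export
zone_occupancy <- function(pose, arena, zone, window = NULL,
                           config = analysis_config()) {
  pc <- pose_clean(pose, config)
  sel <- pc$valid
  if (!is.null(window)) sel <- sel & pc$t >= window[1] & pc$t < window[2]
  if (!any(sel)) return(NA_real_)
  r <- arena$zones[[zone]]
  mean(point_in_rect(pc$x[sel, "head_center"], pc$y[sel, "head_center"], r))
}
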