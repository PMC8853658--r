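# Event-aligned Z-scored PSTHs and response classification.
#
# Counts are averaged across events in half-open bins; the baseline is the
# n_baseline_bins bins immediately preceding onset, and the Z-score uses the
# population (n-denominator) SD of those baseline bin means so results are
# reproducible bit-for-bit.

#' Event-aligned Z-scored PSTH
#'
#' Bins cover `[-n_baseline_bins * psth_bin, response_window)` around each
#' event onset; spike counts are averaged across events and Z-scored against
#' the mean and population SD of the pre-onset baseline bins. If the baseline
#' SD is zero, Z is 0 where the bin mean equals the baseline mean and a
#' signed infinity sentinel elsewhere (flagged in `degenerate`).
#'
#' @param unit a [spike_train].
#' @param events an [event_series] with at least two events, each with the
#'   full baseline of pre-onset recording available.
#' @param config an [analysis_config].
#' @return object of class `zpsth` with fields `bin_edges` (relative to
#'   onset), `mean_count`, `baseline_mean`, `baseline_sd`, `z`, `n_events`.
#' @export
compute_zpsth <- function(unit, events, config = analysis_config()) {
  onsets <- events$onsets
  if (length(onsets) < 2) stopf("compute_zpsth requires >= 2 events")
  bw <- config$psth_bin
  nb <- config$n_baseline_bins
  pre <- nb * bw
  short <- onsets - pre < unit$t_start
  if (any(short))
    stopf("insufficient pre-onset recording for event(s) at %s s",
          paste(format(onsets[short]), collapse = ", "))
  edges <- seq(-pre, config$response_window, by = bw)
  mean_count <- mean_counts_by_bin(unit$spike_times, onsets, edges)
  base <- mean_count[seq_len(nb)]
  bm <- mean(base)
  bs <- sd_pop(base)
  if (bs > 0) {
    z <- (mean_count - bm) / bs
    degen <- FALSE
  } else {
    z <- ifelse(mean_count == bm, 0, sign(mean_count - bm) * Inf)
    degen <- any(!is.finite(z))
  }
  structure(list(unit_id = unit$unit_id, event_label = events$label,
                 phase = unique(events$phase)[1], bin_width = bw,
                 bin_edges = edges, n_baseline_bins = nb,
                 mean_count = mean_count, baseline_mean = bm,
                 baseline_sd = bs, z = z, n_events = length(onsets),
                 degenerate = degen),
            class = "zpsth")
}

#' @export
print.zpsth <- function(x, ...) {
  post <- x$z[x$bin_edges[-length(x$bin_edges)] >= 0]
  cat(sprintf("<zpsth %s ~ %s> %d events, %d bins of %g ms; peak |Z| post = %.2f\n",
              x$unit_id, x$event_label, x$n_events,
              length(x$mean_count), 1000 * x$bin_width,
              max(abs(post[is.finite(post)]), 0)))
  invisible(x)
}

#' Plot a Z-scored PSTH
#'
#' @param x a [zpsth][compute_zpsth].
#' @param config an [analysis_config]; its thresholds are drawn as dashed
#'   lines.
#' @param ... passed to [graphics::plot].
#' @export
plot.zpsth <- function(x, config = analysis_config(), ...) {
  mid <- x$bin_edges[-length(x$bin_edges)] + x$bin_width / 2
  zz <- x$z
  zz[!is.finite(zz)] <- NA
  graphics::plot(mid, zz, type = "s", xlab = "time from event (s)",
                 ylab = "Z", main = sprintf("%s ~ %s", x$unit_id,
                                            x$event_label), ...)
  graphics::abline(v = 0, col = "grey40")
  graphics::abline(h = c(config$z_excite, config$z_inhibit), lty = 2,
                   col = c("firebrick", "steelblue"))
  invisible(x)
}

post_bin_index <- function(p) which(p$bin_edges[-length(p$bin_edges)] >= 0)

#' Classify an event-aligned response
#'
#' Excited if Z exceeds `z_excite` in the first two post-onset bins (either
#' bin under the default `any_of_first_two_bins` rule; both bins under
#' `both_of_first_two_bins`); otherwise inhibited if Z falls below
#' `z_inhibit` under the same rule; otherwise none. Excitation takes
#' precedence when both thresholds are crossed across the two bins. Excited
#' responses receive a temporal profile via [classify_temporal_profile].
#'
#' @param p a [zpsth][compute_zpsth] with at least two post-onset bins.
#' @param config an [analysis_config].
#' @return one-row data.frame of class `response_record`: `unit_id`,
#'   `event_label`, `phase`, `direction`, `profile`, `auc_pos`, `auc_neg`,
#'   `onset_bin` (1-based post-onset bin of first crossing, NA if none).
#' @export
classify_event_response <- function(p, config = analysis_config()) {
  post <- post_bin_index(p)
  if (length(post) < 2) stopf("need >= 2 post-onset bins")
  z12 <- p$z[post[1:2]]
  comb <- if (config$detection_rule == "any_of_first_two_bins") any else all
  excited <- comb(z12 > config$z_excite)
  inhibited <- !excited && comb(z12 < config$z_inhibit)
  direction <- if (excited) "excited" else if (inhibited) "inhibited" else
    "none"
  onset_bin <- NA_integer_
  if (excited) onset_bin <- which(z12 > config$z_excite)[1]
  if (inhibited) onset_bin <- which(z12 < config$z_inhibit)[1]
  rec <- data.frame(unit_id = p$unit_id, event_label = p$event_label,
                    phase = p$phase, direction = direction,
                    profile = "na",
                    auc_pos = response_auc(p, "positive", config),
                    auc_neg = response_auc(p, "negative", config),
                    onset_bin = onset_bin)
  if (excited) rec$profile <- classify_temporal_profile(p, rec, config)
  class(rec) <- c("response_record", "data.frame")
  rec
}

#' Temporal profile of an excitatory response
#'
#' Duration is the longest run of consecutive bins with Z above `z_excite`
#' that intersects the first two post-onset bins, within the first 3 s,
#' multiplied by the bin width: `transient` below `transient_max` (600 ms),
#' `sustained` at or above `sustained_min` (900 ms), `intermediate` for the
#' in-between case (exactly 600 ms at 300-ms bins).
#'
#' @param p a [zpsth][compute_zpsth].
#' @param record a `response_record` with `direction == "excited"`.
#' @param config an [analysis_config].
#' @return `"transient"`, `"intermediate"` or `"sustained"`.
#' @export
classify_temporal_profile <- function(p, record, config = analysis_config()) {
  if (!identical(record$direction, "excited"))
    stopf("temporal profile is defined only for excited responses")
  post <- post_bin_index(p)
  lefts <- p$bin_edges[post]
  post <- post[lefts < config$response_window]
  sig <- p$z[post] > config$z_excite
  runs <- true_runs(sig)
  runs <- runs[runs$start <= 2, , drop = FALSE] # must touch bins 1-2
  dur <- if (nrow(runs)) max(runs$end - runs$start + 1) * p$bin_width else 0
  if (dur < config$transient_max) "transient"
  else if (dur >= config$sustained_min) "sustained"
  else "intermediate"
}

#' Signed area under the Z curve
#'
#' Sum over post-onset bins in `[0, response_window)` of the positive
#' (or negative) part of Z, times the bin width. Infinite sentinel bins from
#' a degenerate baseline are excluded.
#'
#' @param p a [zpsth][compute_zpsth].
#' @param sign `"positive"` or `"negative"`.
#' @param config an [analysis_config].
#' @return AUC in Z-seconds (>= 0 for positive, <= 0 for negative).
#' @export
response_auc <- function(p, sign = c("positive", "negative"),
                         config = analysis_config()) {
  sign <- match.arg(sign)
  post <- post_bin_index(p)
  lefts <- p$bin_edges[post]
  z <- p$z[post[lefts < config$response_window]]
  z <- z[is.finite(z)]
  if (sign == "positive") sum(pmax(z, 0)) * p$bin_width
  else sum(pmin(z, 0)) * p$bin_width
}

#' Spontaneous-rate change between two windows
#'
#' Compares spike counts in 1-s sub-bins of a phase window against a baseline
#' window (both of `spont_window` length, conventionally the last 30 s of a
#' phase versus the 30 s before session start) with a two-sided rank-sum test
#' at alpha = 0.05; direction is the sign of the mean difference.
#'
#' @param unit a [spike_train].
#' @param baseline_window,phase_window c(start, end), seconds.
#' @param config an [analysis_config].
#' @return `"excited"`, `"inhibited"` or `"none"`.
#' @export
classify_spontaneous_change <- function(unit, baseline_window, phase_window,
                                        config = analysis_config()) {
  w <- config$spont_window
  for (win in list(baseline_window, phase_window)) {
    if (abs(diff(win) - w) > 1e-9)
      stopf("windows must be %g s long", w)
    if (win[1] < unit$t_start || win[2] > unit$t_stop)
      stopf("window [%g, %g) outside recording", win[1], win[2])
  }
  cb <- count_in_windows(unit$spike_times,
                         seq(baseline_window[1], baseline_window[2] - 1), 1)
  cp <- count_in_windows(unit$spike_times,
                         seq(phase_window[1], phase_window[2] - 1), 1)
  p <- stats::wilcox.test(cp, cb, exact = FALSE)$p.value
  if (is.na(p) || p >= 0.05) return("none")
  if (mean(cp) > mean(cb)) "excited" else "inhibited"
}

#' Track response directions across phases
#'
#' @param records a data.frame of response records (rbind of
#'   [classify_event_response] rows) with columns `unit_id`, `phase`,
#'   `direction`.
#' @param phases phase order; defaults to the order of first appearance.
#' @return list with `per_unit` (wide data.frame, one direction column per
#'   phase), `marginals` (counts of excited/inhibited/none per phase) and
#'   `transitions` (per consecutive phase pair, counts of direction pairs).
#'   Units missing from any phase are dropped with a warning.
#' @export
track_across_phases <- function(records, phases = unique(records$phase)) {
  if (!nrow(records))
    return(list(per_unit = data.frame(unit_id = character()),
                marginals = data.frame(), transitions = list()))
  wide <- data.frame(unit_id = unique(records$unit_id))
  for (ph in phases) {
    sub <- records[records$phase == ph, c("unit_id", "direction")]
    wide[[ph]] <- sub$direction[match(wide$unit_id, sub$unit_id)]
  }
  miss <- !stats::complete.cases(wide)
  if (any(miss)) {
    warning(sprintf("excluding %d unit(s) missing in some phase: %s",
                    sum(miss), paste(wide$unit_id[miss], collapse = ", ")))
    wide <- wide[!miss, , drop = FALSE]
  }
  lv <- c("excited", "inhibited", "none")
  marg <- do.call(rbind, lapply(phases, function(ph)
    data.frame(phase = ph, direction = lv,
               n = as.vector(table(factor(wide[[ph]], levels = lv))))))
  trans <- list()
  if (length(phases) > 1) {
    for (i in seq_len(length(phases) - 1)) {
      a <- phases[i]; b <- phases[i + 1]
      trans[[paste(a, b, sep = "->")]] <-
        table(from = factor(wide[[a]], levels = lv),
              to = factor(wide[[b]], levels = lv))
    }
  }
  list(per_unit = wide, marginals = marg, transitions = trans)
}
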