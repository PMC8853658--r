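# End-to-end driver: phenotype -> cue responses per phase -> photoid ->
# behavior -> spectral -> group statistics, with CSV tables and a summary.

# Cue-aligned response records for every unit, per phase with cues.
session_responses <- function(s, config) {
  cues <- session_events(s, "food_cue")
  if (is.null(cues)) return(NULL)
  out <- list()
  for (ph in intersect(c("reward", "conflict"), unique(cues$phase))) {
    sel <- cues$phase == ph
    if (sum(sel) < 2) next
    es <- event_series("food_cue", cues$onsets[sel], cues$durations[sel],
                       ph, cues$rewarded[sel])
    for (u in s$units) {
      rec <- classify_event_response(compute_zpsth(u, es, config), config)
      rec$subject_id <- s$subject_id
      out[[length(out) + 1]] <- rec
    }
  }
  do.call(rbind, out)
}

session_behavior <- function(s, config) {
  bouts <- rbind(detect_freezing(s$pose, config),
                 detect_avoidance(s$pose, s$arena, config),
                 detect_risk_assessment(s$pose, s$arena, config = config))
  conflict <- s$phase_intervals$conflict
  feats <- c(
    freezing_pct = 100 * bout_time_fraction(
      bouts[bouts$type == "freezing", ], conflict),
    avoidance_pct = 100 * bout_time_fraction(
      bouts[bouts$type == "avoidance", ], conflict),
    food_area_pct = 100 * zone_occupancy(s$pose, s$arena, "food", conflict,
                                         config),
    risk_pct = 100 * bout_time_fraction(
      bouts[bouts$type == "risk_assessment", ], conflict))
  list(bouts = bouts, features = feats)
}

#' Run the full analysis pipeline over a set of sessions
#'
#' Executes, per session: phenotype classification, cue-aligned response
#' classification per phase, photoidentification when laser pulses are
#' present, behavior detection when pose and arena are present, and spectral
#' band summaries when a field potential is present. Group statistics
#' (responsive-proportion Fisher tests between phenotypes and phases, and a
#' behavioral PCA when behavior features exist for at least three subjects)
#' are computed over the cohort. All tables are written to `out` along with
#' `summary.json`. Per-session failures are logged and skipped; it is an
#' error only if every session fails.
#'
#' @param sessions list of [session] objects and/or session directory paths.
#' @param config an [analysis_config].
#' @param out output directory (optional: NULL computes without writing).
#' @return the summary as a list (invisibly when writing).
#' @export
run_pipeline <- function(sessions, config = analysis_config(), out = NULL) {
  resp <- list(); photo <- list(); bouts <- list(); bands <- list()
  feats <- list(); phen <- character(); failed <- character()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    res <- tryCatch({
      if (is.character(s)) s <- load_session(s, config)
      s$phenotype <- classify_phenotype(s)
      phen[s$subject_id] <- s$phenotype
      r <- session_responses(s, config)
      if (!is.null(r)) resp[[s$subject_id]] <- r
      pulses <- session_events(s, "laser_pulse")
      if (!is.null(pulses)) {
        pr <- lapply(s$units, function(u) {
          lr <- photoidentify(u, pulses, config = config)
          data.frame(subject_id = s$subject_id, unit_id = lr$unit_id,
                     latency_ms = 1000 * lr$latency,
                     ff_before = lr$ff_before, ff_after = lr$ff_after,
                     ff_ratio = lr$ff_ratio,
                     photoidentified = lr$photoidentified, class = lr$class)
        })
        photo[[s$subject_id]] <- do.call(rbind, pr)
      }
      if (!is.null(s$pose) && !is.null(s$arena)) {
        sb <- session_behavior(s, config)
        if (nrow(sb$bouts)) {
          sb$bouts$subject_id <- s$subject_id
          bouts[[s$subject_id]] <- sb$bouts
        }
        feats[[s$subject_id]] <- sb$features
      }
      if (!is.null(s$lfp)) {
        ps <- compute_psd(s$lfp, config = config)
        bf <- band_fractions(ps$freq, ps$psd, config$bands)
        bands[[s$subject_id]] <- data.frame(subject_id = s$subject_id,
                                            band = names(bf),
                                            pct = as.numeric(bf),
                                            phenotype = s$phenotype)
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("session %d failed: %s", i, conditionMessage(e)))
      FALSE
    })
    if (!isTRUE(res))
      failed <- c(failed, if (is.character(sessions[[i]])) sessions[[i]] else
        paste0("session_", i))
  }
  if (length(failed) == length(sessions))
    stopf("all %d sessions failed", length(sessions))
  responses <- if (length(resp)) do.call(rbind, resp) else NULL
  summary <- list(n_sessions = length(sessions) - length(failed),
                  failed = failed,
                  phenotype_counts = as.list(table(phen)))
  # responsive proportions per phenotype and phase, plus Fisher contrasts
  if (!is.null(responses)) {
    responses$phenotype <- phen[responses$subject_id]
    tab <- list()
    for (g in unique(responses$phenotype)) for (ph in unique(responses$phase)) {
      sub <- responses[responses$phenotype == g & responses$phase == ph, ]
      if (!nrow(sub)) next
      tab[[paste(g, ph, sep = ".")]] <-
        list(k = sum(sub$direction != "none"), n = nrow(sub))
    }
    summary$responsive <- tab
    ft <- list()
    pair <- function(a, b) {
      if (!is.null(tab[[a]]) && !is.null(tab[[b]]))
        fisher_proportions(tab[[a]]$k, tab[[a]]$n, tab[[b]]$k,
                           tab[[b]]$n)[c("odds_ratio", "p_value")]
    }
    ft$presser_reward_vs_conflict <- pair("presser.reward",
                                          "presser.conflict")
    ft$non_presser_reward_vs_conflict <- pair("non_presser.reward",
                                              "non_presser.conflict")
    ft$reward_presser_vs_non_presser <- pair("presser.reward",
                                             "non_presser.reward")
    summary$fisher <- ft[!vapply(ft, is.null, TRUE)]
  }
  if (length(feats) >= 3) {
    fm <- as.data.frame(do.call(rbind, feats))
    ok <- vapply(fm, function(v) stats::sd(v) > 0 && !anyNA(v), TRUE)
    if (sum(ok) >= 2) {
      p <- pca_behavior(fm[, ok, drop = FALSE])
      summary$pca <- list(explained_variance = p$explained_variance,
                          pc1_loadings = as.list(p$loadings[, 1]))
    }
  }
  if (length(bands)) {
    bd <- do.call(rbind, bands)
    summary$band_means <- lapply(split(bd$pct, list(bd$phenotype, bd$band),
                                       drop = TRUE), mean)
  }
  if (!is.null(out)) {
    tables <- list()
    if (!is.null(responses)) tables$responses <-
      responses[, c("subject_id", "unit_id", "event_label", "phase",
                    "direction", "profile", "auc_pos", "auc_neg",
                    "onset_bin")]
    if (length(photo)) tables$photoid <- do.call(rbind, photo)
    if (length(bouts)) tables$bouts <- do.call(rbind, bouts)
    if (length(bands)) tables$bands <- do.call(rbind, bands)
    save_results(tables, out, config)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
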