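#' Analysis configuration
#'
#' Collects every numeric threshold and window used by the pipeline. The
#' defaults implement the standard analysis: event-aligned peristimulus time
#' histograms are Z-scored against 20 pre-event bins of 300 ms; excitation is
#' called at Z > 2.58 (two-sided p < 0.01), inhibition at Z < -1.96 (p < 0.05)
#' in the first two post-event bins; laser responses are scored in 1-ms bins
#' against a 20-ms pre-pulse baseline at Z > 3.29 (p < 0.001); excitatory
#' responses shorter than 600 ms are transient, those of 900 ms or more are
#' sustained. Freezing is stillness of all tracked parts within 1.05 pixels
#' for strictly more than 500 ms. Behavior onsets feed the neural alignment
#' only if the bout lasted more than 1 s and no same-type bout occurred in
#' the preceding 6 s. Frequency bands partition 0-100 Hz into delta (0-4),
#' theta (4-10), alpha (10-14), beta (14-35) and gamma (35-100 Hz).
#'
#' @param psth_bin PSTH bin width, seconds.
#' @param n_baseline_bins number of pre-event baseline bins.
#' @param z_excite,z_inhibit,z_photo Z-score thresholds for excitation,
#'   inhibition, and laser-evoked responses.
#' @param response_window post-event analysis window, seconds.
#' @param transient_max responses shorter than this are transient, seconds.
#' @param sustained_min responses at least this long are sustained, seconds.
#' @param laser_bin laser PSTH bin width, seconds.
#' @param laser_baseline pre-pulse baseline length, seconds.
#' @param photoid_window default latency cut for photoidentification, seconds.
#' @param laser_search_max latency search horizon after pulse onset, seconds.
#' @param freeze_min_dur minimum stillness duration (strict), seconds.
#' @param freeze_tol per-frame displacement tolerance for stillness, pixels.
#' @param bout_min_dur minimum bout duration kept by [filter_onsets], seconds.
#' @param bout_refractory same-behavior exclusion window before an onset, s.
#' @param behavior_align_window interval criterion around behavior onset, s.
#' @param behavior_align_bin bin width for behavior-aligned histograms, s.
#' @param behavior_baseline baseline length for behavior-aligned
#'   histograms, seconds (ends `behavior_align_window` before onset).
#' @param min_behavior_onsets minimum onsets required per behavior.
#' @param spont_window window length for spontaneous-rate comparisons, s.
#' @param stretch_z body-length threshold for risk assessment, in session SDs.
#' @param frame_rate assumed video frame rate when not recorded, Hz.
#' @param likelihood_cutoff pose likelihood below which frames are masked.
#' @param pose_gap_max longest masked gap bridged by interpolation, seconds.
#' @param bands named list of c(lo, hi) band edges in Hz.
#' @param psd_segment Welch segment length, seconds.
#' @param psd_overlap Welch segment overlap fraction.
#' @param detection_rule `"any_of_first_two_bins"` (default) or
#'   `"both_of_first_two_bins"`: whether one or both of the first two
#'   post-event bins must cross threshold.
#' @param rng_seed integer seed recorded in result manifests.
#' @return an object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(psth_bin = 0.300,
                            n_baseline_bins = 20L,
                            z_excite = 2.58,
                            z_inhibit = -1.96,
                            z_photo = 3.29,
                            response_window = 3.0,
                            transient_max = 0.600,
                            sustained_min = 0.900,
                            laser_bin = 0.001,
                            laser_baseline = 0.020,
                            photoid_window = 0.006,
                            laser_search_max = 0.012,
                            freeze_min_dur = 0.500,
                            freeze_tol = 1.05,
                            bout_min_dur = 1.0,
                            bout_refractory = 6.0,
                            behavior_align_window = 0.600,
                            behavior_align_bin = 0.100,
                            behavior_baseline = 6.0,
                            min_behavior_onsets = 6L,
                            spont_window = 30,
                            stretch_z = 1.0,
                            frame_rate = 30,
                            likelihood_cutoff = 0.9,
                            pose_gap_max = 0.5,
                            bands = list(delta = c(0, 4), theta = c(4, 10),
                                         alpha = c(10, 14), beta = c(14, 35),
                                         gamma = c(35, 100)),
                            psd_segment = 2,
                            psd_overlap = 0.5,
                            detection_rule = c("any_of_first_two_bins",
                                               "both_of_first_two_bins"),
                            rng_seed = 1L) {
  detection_rule <- match.arg(detection_rule)
  cfg <- list(
    psth_bin = psth_bin, n_baseline_bins = as.integer(n_baseline_bins),
    z_excite = z_excite, z_inhibit = z_inhibit, z_photo = z_photo,
    response_window = response_window, transient_max = transient_max,
    sustained_min = sustained_min, laser_bin = laser_bin,
    laser_baseline = laser_baseline, photoid_window = photoid_window,
    laser_search_max = laser_search_max, freeze_min_dur = freeze_min_dur,
    freeze_tol = freeze_tol, bout_min_dur = bout_min_dur,
    bout_refractory = bout_refractory,
    behavior_align_window = behavior_align_window,
    behavior_align_bin = behavior_align_bin,
    behavior_baseline = behavior_baseline,
    min_behavior_onsets = as.integer(min_behavior_onsets),
    spont_window = spont_window, stretch_z = stretch_z,
    frame_rate = frame_rate, likelihood_cutoff = likelihood_cutoff,
    pose_gap_max = pose_gap_max, bands = bands, psd_segment = psd_segment,
    psd_overlap = psd_overlap, detection_rule = detection_rule,
    rng_seed = as.integer(rng_seed)
  )
  win <- c("psth_bin", "response_window", "transient_max", "sustained_min",
           "laser_bin", "laser_baseline", "photoid_window", "laser_search_max",
           "freeze_min_dur", "bout_min_dur", "bout_refractory",
           "behavior_align_window", "behavior_align_bin", "behavior_baseline",
           "spont_window", "psd_segment")
  bad <- win[vapply(cfg[win], function(v) !is.numeric(v) || v <= 0, TRUE)]
  if (length(bad)) stopf("non-positive window/bin parameter(s): %s",
                         paste(bad, collapse = ", "))
  if (cfg$n_baseline_bins < 2L) stopf("n_baseline_bins must be >= 2")
  bm <- do.call(rbind, cfg$bands)
  if (any(bm[, 2] <= bm[, 1])) stopf("bands must have lo < hi")
  o <- order(bm[, 1])
  if (any(bm[o, 1][-1] < bm[o, 2][-nrow(bm)]))
    stopf("bands must be non-overlapping")
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  PSTH: %d baseline bins of %g ms; window %g s; rule %s\n",
              x$n_baseline_bins, 1000 * x$psth_bin, x$response_window,
              x$detection_rule))
  cat(sprintf("  thresholds: Z>%g excite, Z<%g inhibit, Z>%g photo\n",
              x$z_excite, x$z_inhibit, x$z_photo))
  cat(sprintf("  profiles: transient < %g ms, sustained >= %g ms\n",
              1000 * x$transient_max, 1000 * x$sustained_min))
  cat(sprintf("  bands: %s\n", paste(sprintf("%s %g-%g", names(x$bands),
              sapply(x$bands, `[`, 1), sapply(x$bands, `[`, 2)),
              collapse = ", ")))
  invisible(x)
}

#' Read or write an analysis configuration as YAML
#'
#' `write_config()` mirrors the full configuration; `read_config()` applies
#' the file's fields over the defaults, so partial files are valid.
#'
#' @param config an `analysis_config`.
#' @param path YAML file path.
#' @return `read_config()` returns an `analysis_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$bands)) x$bands <- lapply(x$bands, as.numeric)
  do.call(analysis_config, x)
}
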