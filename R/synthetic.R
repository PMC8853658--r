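# Synthetic sessions with known ground truth. Spiking is a thinned
# inhomogeneous Poisson process with a 2-ms absolute refractory period and
# dead-time-compensated intensity, so the realized rate matches the nominal
# rate. Laser-evoked responses are all-or-none short bursts (see vignette).

#' Specification of one synthetic unit
#'
#' @param baseline_rate spontaneous rate, Hz.
#' @param response_kind `none`, `excited_transient`, `excited_sustained` or
#'   `inhibited` (cue-evoked rate modulation).
#' @param response_gain multiplicative rate factor during the response window
#'   (defaults: 3 for excited kinds, 0.1 for inhibited, 1 for none).
#' @param response_duration response length, seconds (defaults: 0.3 transient,
#'   1.2 sustained/inhibited).
#' @param laser_class `direct` (opsin-driven, ~3.3 ms latency), `indirect`
#'   (synaptic, ~21 ms) or `unresponsive`.
#' @param laser_latency_mean,laser_latency_sd mean and per-pulse jitter of
#'   the evoked first-spike latency, seconds. The jitter is the within-unit
#'   trial-to-trial SD (~0.5 ms for opsin-driven responses); across-unit
#'   latency dispersion is modelled by drawing each unit's
#'   `laser_latency_mean` from the population distribution.
#' @param p_spike probability a laser pulse evokes a response.
#' @param burst_prob probability an evoked response is a short high-frequency
#'   burst rather than a single spike (all-or-none burst model).
#' @param burst_size number of spikes in an evoked burst.
#' @param refractory absolute refractory period, seconds.
#' @return object of class `unit_spec`.
#' @export
unit_spec <- function(baseline_rate = 5,
                      response_kind = c("none", "excited_transient",
                                        "excited_sustained", "inhibited"),
                      response_gain = NULL, response_duration = NULL,
                      laser_class = c("unresponsive", "direct", "indirect"),
                      laser_latency_mean = NULL, laser_latency_sd = NULL,
                      p_spike = 0.9, burst_prob = 0.45, burst_size = 4,
                      refractory = 0.002) {
  response_kind <- match.arg(response_kind)
  laser_class <- match.arg(laser_class)
  if (is.null(response_gain))
    response_gain <- switch(response_kind, none = 1, inhibited = 0.1, 3)
  if (is.null(response_duration))
    response_duration <- switch(response_kind, excited_transient = 0.3, 1.2)
  if (is.null(laser_latency_mean))
    laser_latency_mean <- switch(laser_class, direct = 0.0033,
                                 indirect = 0.021, NA_real_)
  if (is.null(laser_latency_sd))
    laser_latency_sd <- switch(laser_class, direct = 0.0005,
                               indirect = 0.0015, NA_real_)
  if (baseline_rate <= 0) stopf("baseline_rate must be > 0")
  if (response_gain < 0) stopf("response_gain must be >= 0")
  if (!is.na(laser_latency_mean) && (laser_latency_mean < 0 ||
                                     laser_latency_sd < 0))
    stopf("laser latency parameters must be >= 0")
  structure(list(baseline_rate = baseline_rate, response_kind = response_kind,
                 response_gain = response_gain,
                 response_duration = response_duration,
                 laser_class = laser_class,
                 laser_latency_mean = laser_latency_mean,
                 laser_latency_sd = laser_latency_sd, p_spike = p_spike,
                 burst_prob = burst_prob, burst_size = burst_size,
                 refractory = refractory),
            class = "unit_spec")
}

# Iteratively drop spikes closer than tau to their (kept) predecessor.
enforce_refractory <- function(times, tau) {
  repeat {
    if (length(times) < 2) return(times)
    bad <- which(diff(times) < tau) + 1L
    if (!length(bad)) return(times)
    # drop only the first offender of each consecutive run, then re-check
    bad <- bad[c(TRUE, diff(bad) > 1L)]
    times <- times[-bad]
  }
}

#' Generate a spike train from a unit specification
#'
#' Inhomogeneous Poisson by thinning with dead-time-compensated intensity
#' (hazard r/(1 - r * refractory)), then a 2-ms absolute refractory pass, so
#' the empirical rate converges to the nominal rate. During
#' `[onset, onset + response_duration)` of each responded-to event the rate is
#' `response_gain * baseline_rate`.
#'
#' @param spec a [unit_spec].
#' @param events optional [event_series] the unit responds to.
#' @param duration recording length, seconds.
#' @param seed integer seed.
#' @param unit_id identifier for the resulting train.
#' @param t_start recording start, seconds.
#' @param respond_mask logical per event: which events the unit responds to
#'   (default all). Lets a cohort plant responses that persist in only a
#'   subset of phases.
#' @return a [spike_train].
#' @export
gen_unit <- function(spec, events = NULL, duration, seed,
                     unit_id = "u1", t_start = 0, respond_mask = NULL) {
  gain <- if (spec$response_kind == "none") 1 else spec$response_gain
  r_max <- spec$baseline_rate * max(1, gain)
  if (r_max * spec$refractory >= 1)
    stopf("infeasible unit: rate x refractory >= 1")
  set.seed(seed)
  haz <- function(r) r / (1 - r * spec$refractory)
  lam <- haz(r_max)
  n_cand <- stats::rpois(1, lam * duration)
  cand <- sort(stats::runif(n_cand, t_start, t_start + duration))
  rate <- rep(spec$baseline_rate, length(cand))
  if (!is.null(events) && spec$response_kind != "none" &&
      length(events$onsets)) {
    on <- events$onsets
    if (!is.null(respond_mask)) on <- on[respond_mask]
    for (o in on) {
      hit <- cand >= o & cand < o + spec$response_duration
      rate[hit] <- spec$baseline_rate * gain
    }
  }
  keep <- stats::runif(length(cand)) < haz(rate) / lam
  times <- enforce_refractory(cand[keep], spec$refractory)
  spike_train(unit_id, times, t_start, t_start + duration)
}

#' Generate a photoidentification session fragment
#'
#' Builds the standard stimulation protocol: `n_trains` trains of 10 s of
#' 5-Hz laser pulses (50 pulses per train at 200-ms intervals). Direct and
#' indirect units respond to each pulse with probability `p_spike`, emitting
#' either a single spike or (with probability `burst_prob`) a short
#' high-frequency burst of `burst_size` spikes at ~0.9-ms intervals, starting
#' at the unit's latency (floored at 1.5 ms). The all-or-none burst mixture
#' is what gives reliable opsin-driven responses their supra-baseline count
#' dispersion in the post-pulse window (see the methods vignette). Evoked
#' spikes are added to baseline spiking; collisions closer than 0.5 ms are
#' dropped.
#'
#' @param specs list of [unit_spec]s.
#' @param seed integer seed.
#' @param n_trains,pulses_per_train,pulse_interval protocol shape.
#' @param train_gap silent gap between trains, seconds.
#' @return list with `units` (list of [spike_train]) and `pulses`
#'   (an [event_series] with train ids).
#' @export
gen_laser_session <- function(specs, seed, n_trains = 10,
                              pulses_per_train = 50, pulse_interval = 0.2,
                              train_gap = 10) {
  train_len <- pulses_per_train * pulse_interval
  starts <- 10 + (seq_len(n_trains) - 1) * (train_len + train_gap)
  onsets <- as.vector(outer((seq_len(pulses_per_train) - 1) * pulse_interval,
                            starts, `+`))
  train <- rep(seq_len(n_trains), each = pulses_per_train)
  o <- order(onsets)
  pulses <- event_series("laser_pulse", onsets[o], 0.005, phase = "post",
                         train = train[o])
  t_stop <- max(onsets) + 10
  units <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    base <- gen_unit(sp, NULL, t_stop, child_seed(seed, i, 1),
                     unit_id = sprintf("u%02d", i))
    times <- base$spike_times
    if (sp$laser_class != "unresponsive") {
      set.seed(child_seed(seed, i, 2))
      resp <- stats::runif(length(onsets)) < sp$p_spike
      for (k in which(resp)) {
        lat <- max(stats::rnorm(1, sp$laser_latency_mean, sp$laser_latency_sd),
                   1.5e-3) # conduction + spike initiation floor
        nb <- if (stats::runif(1) < sp$burst_prob) sp$burst_size else 1L
        isi <- 9e-4 * stats::runif(nb, 0.85, 1.15)
        times <- c(times, onsets[k] + lat + cumsum(isi) - isi[1])
      }
      times <- enforce_refractory(sort(times), 5e-4)
      times <- times[times <= t_stop]
    }
    units[[i]] <- spike_train(sprintf("u%02d", i), times, 0, t_stop)
  }
  list(units = units, pulses = pulses)
}

#' Default arena geometry
#'
#' A 600 x 260 px arena (10 px/cm): hidden area on the left (200 px), center,
#' and food area on the right (120 px), with an 80-px slot in the divider.
#'
#' @return an [arena_layout].
#' @export
default_arena <- function() {
  arena_layout(zones = list(hidden = c(0, 200, 0, 260),
                            center = c(200, 480, 0, 260),
                            food = c(480, 600, 0, 260)),
               slot = rbind(c(200, 90), c(200, 170)))
}

#' Generate a pose track from a behavior script
#'
#' Renders a smooth random walk in the open area with per-frame jitter above
#' the stillness tolerance, overridden during scripted bouts: `freezing`
#' freezes all parts (jitter ~0.15 px), `avoidance` places the animal inside
#' the hidden zone, `risk_assessment` places hindquarters in the hidden zone
#' with the nose stretched through the slot.
#'
#' @param script data.frame with columns `type`, `onset`, `duration` (s);
#'   may have zero rows. Overlapping bouts of different types are an error.
#' @param arena an [arena_layout].
#' @param duration track length, seconds.
#' @param frame_rate frames per second.
#' @param seed integer seed.
#' @param noise_sd per-part jitter outside freezing, pixels.
#' @param dropout_rate fraction of frames given low likelihood (0.3).
#' @return a [pose_track].
#' @export
gen_pose <- function(script, arena = default_arena(), duration,
                     frame_rate = 30, seed = 1, noise_sd = 3,
                     dropout_rate = 0) {
  if (nrow(script) > 1) {
    s <- script[order(script$onset), ]
    ends <- s$onset + s$duration
    if (any(s$onset[-1] < ends[-nrow(s)]))
      stopf("overlapping incompatible bouts in behavior script")
  }
  set.seed(seed)
  n <- floor(duration * frame_rate)
  tms <- (seq_len(n) - 1) / frame_rate
  hz <- arena$zones$hidden
  div_x <- max(hz[1:2])       # divider faces the open area
  slot_y <- sort(arena$slot[, 2])
  open_lo <- c(div_x + 80, 50)
  open_hi <- c(arena$zones$food[2] - 60, arena$zones$food[4] - 50)
  # smooth centroid walk confined to the open area
  step <- matrix(stats::rnorm(2 * n, 0, 2.5), n, 2)
  cx <- numeric(n); cy <- numeric(n)
  pos <- c(mean(c(open_lo[1], open_hi[1])), mean(c(open_lo[2], open_hi[2])))
  for (i in seq_len(n)) {
    pos <- pos + step[i, ]
    pos <- pmin(pmax(pos, open_lo), open_hi)
    cx[i] <- pos[1]; cy[i] <- pos[2]
  }
  theta <- cumsum(stats::rnorm(n, 0, 0.15))
  ux <- cos(theta); uy <- sin(theta)
  offsets <- list(nose = 45, head_center = 28, left_ear = 22,
                  right_ear = 22, spine = 0, tail_base = -42)
  perp <- c(nose = 0, head_center = 0, left_ear = 12, right_ear = -12,
            spine = 0, tail_base = 0)
  jit <- rep(noise_sd, n)
  # apply script overrides
  for (k in seq_len(nrow(script))) {
    b <- script[k, ]
    idx <- which(tms >= b$onset & tms < b$onset + b$duration)
    if (!length(idx)) next
    if (b$type == "freezing") {
      cx[idx] <- cx[idx[1]]; cy[idx] <- cy[idx[1]]
      ux[idx] <- ux[idx[1]]; uy[idx] <- uy[idx[1]]
      jit[idx] <- 0.15
    } else if (b$type == "avoidance") {
      cx[idx] <- mean(hz[1:2]) - 20 + cumsum(stats::rnorm(length(idx), 0, 0.5))
      cy[idx] <- mean(hz[3:4]) + cumsum(stats::rnorm(length(idx), 0, 0.5))
      ux[idx] <- -1; uy[idx] <- 0 # facing away from the divider
      jit[idx] <- 1.5
    } else if (b$type == "risk_assessment") {
      cx[idx] <- div_x - 38
      cy[idx] <- mean(slot_y)
      ux[idx] <- 1; uy[idx] <- 0  # peeking toward the open area
      jit[idx] <- 1.5
    } else stopf("unknown scripted behavior type: %s", b$type)
  }
  stretch <- rep(1, n)
  for (k in seq_len(nrow(script))) {
    b <- script[k, ]
    if (b$type == "risk_assessment") {
      idx <- which(tms >= b$onset & tms < b$onset + b$duration)
      stretch[idx] <- 1.8
    }
  }
  parts <- POSE_PARTS
  x <- matrix(NA_real_, n, 6, dimnames = list(NULL, parts))
  y <- matrix(NA_real_, n, 6, dimnames = list(NULL, parts))
  for (p in parts) {
    off <- offsets[[p]] * (if (offsets[[p]] != 0) stretch else 1)
    x[, p] <- cx + off * ux - perp[p] * uy + stats::rnorm(n, 0, jit)
    y[, p] <- cy + off * uy + perp[p] * ux + stats::rnorm(n, 0, jit)
  }
  lik <- matrix(0.99, n, 6, dimnames = list(NULL, parts))
  if (dropout_rate > 0) {
    drop <- stats::runif(n) < dropout_rate
    lik[drop, ] <- 0.3
  }
  pose_track(tms, frame_rate, x, y, lik)
}

#' Generate a synthetic field potential
#'
#' 1/f (pink) background noise of unit variance plus one oscillator at 3 Hz
#' (`delta_dominant`) or 7 Hz (`theta_dominant`).
#'
#' @param profile `delta_dominant`, `theta_dominant` or `none`.
#' @param duration seconds.
#' @param fs sampling rate, Hz (>= 200).
#' @param seed integer seed.
#' @param osc_amp oscillator amplitude in background-SD units.
#' @return an [lfp_signal].
#' @export
gen_lfp <- function(profile = c("delta_dominant", "theta_dominant", "none"),
                    duration, fs = 1000, seed = 1, osc_amp = 1.5) {
  profile <- match.arg(profile)
  if (fs < 200) stopf("gen_lfp requires fs >= 200 Hz")
  set.seed(seed)
  n <- floor(duration * fs)
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  shape <- 1 / sqrt(pmax(freqs, 0.5))
  shape[1] <- 0
  half <- shape * (stats::rnorm(length(freqs)) +
                   1i * stats::rnorm(length(freqs)))
  spec <- c(half, Conj(rev(half[2:(n - length(freqs) + 1)])))
  bg <- Re(stats::fft(spec, inverse = TRUE))
  bg <- bg / stats::sd(bg)
  tt <- (seq_len(n) - 1) / fs
  osc <- switch(profile,
                delta_dominant = osc_amp * sin(2 * pi * 3 * tt +
                                               stats::runif(1, 0, 2 * pi)),
                theta_dominant = osc_amp * sin(2 * pi * 7 * tt +
                                               stats::runif(1, 0, 2 * pi)),
                none = 0)
  lfp_signal(bg + osc, fs = fs, t_start = 0)
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study conditions: 12 food cues of 30 s per cue
#' phase with 25-40 s inter-trial intervals; phenotype mix 0.78 pressers;
#' about a third of units cue-responsive in the reward phase, of which 40%
#' retain their response under conflict; pressers carry delta-dominant and
#' non-pressers theta-dominant field potentials.
#'
#' @param n_sessions number of subjects.
#' @param phenotype_mix fraction of pressers.
#' @param n_units units recorded per session.
#' @param p_responsive fraction of cue-responsive units (reward phase).
#' @param p_retain probability a responsive unit stays responsive in conflict.
#' @param excited_frac fraction of responsive units that are excited (the
#'   rest are inhibited); excited units split evenly transient/sustained.
#' @param n_cues cues per cue phase.
#' @param cue_duration seconds.
#' @param iti_range inter-trial interval range, seconds.
#' @param odor_duration odor-phase length, seconds.
#' @param baseline_rates range of unit baseline rates, Hz.
#' @param include_pose,include_lfp render pose tracks / field potentials
#'   (off by default; behavioral ground truth is always generated).
#' @param lfp_fs,lfp_duration field-potential sampling rate and length.
#' @param rng_seed master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sessions = 32, phenotype_mix = 0.78, n_units = 8,
                        p_responsive = 0.33, p_retain = 0.4,
                        excited_frac = 0.6, n_cues = 12, cue_duration = 30,
                        iti_range = c(25, 40), odor_duration = 600,
                        baseline_rates = c(4, 9),
                        include_pose = FALSE, include_lfp = FALSE,
                        lfp_fs = 500, lfp_duration = 60, rng_seed = 1L) {
  stopifnot(phenotype_mix >= 0, phenotype_mix <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# Per-phenotype conflict-phase behavior feature distributions (mean, sd).
# Percent scales clamp to [0, 100]; latency to [0.5, cue_duration] with
# non-pressers at the cue-length ceiling (they never press).
behavior_feature_means <- list(
  presser = c(freezing_pct = 12, avoidance_pct = 15, food_area_pct = 35,
              risk_pct = 5, press_latency_s = 8),
  non_presser = c(freezing_pct = 45, avoidance_pct = 55, food_area_pct = 5,
                  risk_pct = 12, press_latency_s = 30))
behavior_feature_sds <- list(
  presser = c(3.5, 5, 8, 2, 3),
  non_presser = c(8, 10, 3, 4, 0))

draw_features <- function(phenotype, cue_duration) {
  mu <- behavior_feature_means[[phenotype]]
  sd <- behavior_feature_sds[[phenotype]]
  f <- stats::rnorm(5, mu, sd)
  f[1:4] <- pmin(pmax(f[1:4], 0), 100)
  f[5] <- min(max(f[5], 0.5), cue_duration)
  stats::setNames(f, names(mu))
}

# One cue phase: onset schedule with U(iti) gaps, first cue one ITI in.
cue_schedule <- function(phase_start, n_cues, cue_duration, iti_range) {
  iti <- stats::runif(n_cues, iti_range[1], iti_range[2])
  onsets <- phase_start + cumsum(iti) + (seq_len(n_cues) - 1) * cue_duration
  list(onsets = onsets, end = onsets[n_cues] + cue_duration + 15)
}

gen_session <- function(subject_id, phenotype, spec, seed) {
  set.seed(seed)
  pre_end <- 60
  rs <- cue_schedule(pre_end, spec$n_cues, spec$cue_duration, spec$iti_range)
  odor_end <- rs$end + spec$odor_duration
  cs <- cue_schedule(odor_end, spec$n_cues, spec$cue_duration, spec$iti_range)
  t_stop <- cs$end + 120
  phases <- list(pre = c(0, pre_end), reward = c(pre_end, rs$end),
                 odor = c(rs$end, odor_end), conflict = c(odor_end, cs$end),
                 post = c(cs$end, t_stop))
  # presses: reward-phase cues pressed w.p. 0.95; conflict per phenotype
  p_press <- c(reward = 0.95,
               conflict = if (phenotype == "presser") 0.6 else 0)
  cue_on <- c(rs$onsets, cs$onsets)
  cue_ph <- rep(c("reward", "conflict"), each = spec$n_cues)
  pressed <- stats::runif(length(cue_on)) < p_press[cue_ph]
  if (phenotype == "presser" && !any(pressed[cue_ph == "conflict"]))
    pressed[which(cue_ph == "conflict")[sample.int(spec$n_cues, 1)]] <- TRUE
  lat <- pmin(stats::rlnorm(length(cue_on), log(4), 0.5),
              spec$cue_duration - 1)
  press_t <- cue_on[pressed] + lat[pressed]
  press_ph <- cue_ph[pressed]
  cues <- event_series("food_cue", cue_on, spec$cue_duration, cue_ph,
                       rewarded = pressed)
  events <- list(cues)
  if (length(press_t)) {
    o <- order(press_t)
    events <- c(events, list(
      event_series("lever_press", press_t[o], 0, press_ph[o], rewarded = TRUE),
      event_series("dish_entry", press_t[o] + 1.0, 0, press_ph[o],
                   rewarded = TRUE)))
  }
  # units: planted response kinds; conflict retention per unit
  kinds <- c("none", "excited_transient", "excited_sustained", "inhibited")
  pk <- c(1 - spec$p_responsive,
          spec$p_responsive * spec$excited_frac / 2,
          spec$p_responsive * spec$excited_frac / 2,
          spec$p_responsive * (1 - spec$excited_frac))
  unit_kind <- sample(kinds, spec$n_units, replace = TRUE, prob = pk)
  retain <- stats::runif(spec$n_units) < spec$p_retain
  rates <- stats::runif(spec$n_units, spec$baseline_rates[1],
                        spec$baseline_rates[2])
  units <- vector("list", spec$n_units)
  truth_units <- data.frame(subject_id = subject_id,
                            unit_id = sprintf("%s_u%02d", subject_id,
                                              seq_len(spec$n_units)),
                            response_kind = unit_kind,
                            retains_conflict = retain & unit_kind != "none",
                            baseline_rate = rates)
  for (i in seq_len(spec$n_units)) {
    mask <- cue_ph == "reward" | (cue_ph == "conflict" & retain[i])
    us <- unit_spec(baseline_rate = rates[i], response_kind = unit_kind[i])
    units[[i]] <- gen_unit(us, cues, t_stop, child_seed(seed, i),
                           unit_id = truth_units$unit_id[i],
                           respond_mask = mask)
  }
  features <- draw_features(phenotype, spec$cue_duration)
  pose <- NULL
  if (spec$include_pose) {
    script <- data.frame(type = c("freezing", "avoidance", "risk_assessment"),
                         onset = odor_end + c(10, 25, 45),
                         duration = c(3, 8, 3))
    pose <- gen_pose(script, default_arena(), duration = t_stop,
                     frame_rate = 30, seed = child_seed(seed, 101))
  }
  lfp <- NULL
  if (spec$include_lfp) {
    profile <- if (phenotype == "presser") "delta_dominant" else
      "theta_dominant"
    lfp <- gen_lfp(profile, duration = min(spec$lfp_duration, t_stop),
                   fs = spec$lfp_fs, seed = child_seed(seed, 102))
  }
  list(session = session(subject_id, phases, units = units, events = events,
                         phenotype = phenotype, pose = pose, lfp = lfp,
                         arena = if (spec$include_pose) default_arena()),
       truth_units = truth_units,
       features = features)
}

#' Generate a cohort of synthetic sessions with ground truth
#'
#' @param spec a [cohort_spec].
#' @param seed master seed (defaults to `spec$rng_seed`); fans out per
#'   session and unit so any subset is reproducible.
#' @return list of class `cohort` with `sessions` (list of [session]),
#'   and `ground_truth` containing `subjects`, `units` and `features`
#'   data.frames.
#' @export
gen_cohort <- function(spec = cohort_spec(), seed = spec$rng_seed) {
  set.seed(child_seed(seed, 0))
  phen <- ifelse(stats::runif(spec$n_sessions) < spec$phenotype_mix,
                 "presser", "non_presser")
  sessions <- vector("list", spec$n_sessions)
  truth_units <- vector("list", spec$n_sessions)
  feats <- matrix(NA_real_, spec$n_sessions, 5)
  ids <- sprintf("rat%02d", seq_len(spec$n_sessions))
  for (i in seq_len(spec$n_sessions)) {
    g <- gen_session(ids[i], phen[i], spec, child_seed(seed, i))
    sessions[[i]] <- g$session
    truth_units[[i]] <- g$truth_units
    feats[i, ] <- g$features
  }
  colnames(feats) <- names(behavior_feature_means$presser)
  structure(list(
    sessions = sessions,
    ground_truth = list(
      subjects = data.frame(subject_id = ids, phenotype = phen),
      units = do.call(rbind, truth_units),
      features = cbind(data.frame(subject_id = ids, phenotype = phen),
                       as.data.frame(feats)))),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ph <- table(x$ground_truth$subjects$phenotype)
  cat(sprintf("<cohort> %d sessions (%s)\n", length(x$sessions),
              paste(names(ph), ph, sep = ": ", collapse = ", ")))
  invisible(x)
}
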