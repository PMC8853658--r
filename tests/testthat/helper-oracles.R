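# Independent oracles and small fixture builders. Oracles deliberately use
# different algorithms from the package implementation.

# Brute-force Z-PSTH: per-event logical counting, no findInterval.
oracle_zpsth_z <- function(unit, events, config = analysis_config()) {
  bw <- config$psth_bin
  nb <- config$n_baseline_bins
  edges <- seq(-nb * bw, config$response_window, by = bw)
  nbin <- length(edges) - 1
  counts <- matrix(0, length(events$onsets), nbin)
  for (e in seq_along(events$onsets)) {
    rel <- unit$spike_times - events$onsets[e]
    for (b in seq_len(nbin))
      counts[e, b] <- sum(rel >= edges[b] & rel < edges[b + 1])
  }
  mc <- colMeans(counts)
  base <- mc[seq_len(nb)]
  bm <- mean(base)
  bs <- sqrt(mean((base - bm)^2))
  if (bs == 0) return(ifelse(mc == bm, 0, sign(mc - bm) * Inf))
  (mc - bm) / bs
}

# Exhaustive triangle scan: explicit point-to-line distance over every bin.
oracle_triangle <- function(hist) {
  n <- length(hist)
  if (n == 1 || sum(hist > 0) == 1) return(as.integer(which.max(hist) - 1))
  xn <- (seq_len(n) - 1) / (n - 1)
  yn <- (hist - min(hist)) / (max(hist) - min(hist))
  pk <- which.max(hist)
  x1 <- xn[pk]; y1 <- yn[pk]; x2 <- xn[n]; y2 <- yn[n]
  best <- -1; arg <- pk
  for (i in pk:n) {
    # distance from point i to the segment-supporting line through 1 and 2
    num <- abs((y2 - y1) * xn[i] - (x2 - x1) * yn[i] + x2 * y1 - y2 * x1)
    den <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
    d <- if (den == 0) 0 else num / den
    if (d > best + 1e-9) { best <- d; arg <- i }
  }
  as.integer(arg - 1)
}

# Exact two-sided Fisher p by exhaustive enumeration over the hypergeometric
# support with fixed margins, using choose() directly.
oracle_fisher_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2 # first-column margin
  prob <- function(a) choose(n1, a) * choose(n2, m - a) / choose(n1 + n2, m)
  support <- max(0, m - n2):min(n1, m)
  probs <- vapply(support, prob, numeric(1))
  p_obs <- prob(k1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Construct a zpsth object directly from a post-onset Z vector (baseline
# bins at exactly 0) for rule tests.
make_zpsth <- function(z_post, config = analysis_config()) {
  bw <- config$psth_bin
  nb <- config$n_baseline_bins
  edges <- seq(-nb * bw, length(z_post) * bw, by = bw)
  structure(list(unit_id = "fix", event_label = "food_cue", phase = "reward",
                 bin_width = bw, bin_edges = edges, n_baseline_bins = nb,
                 mean_count = c(rep(1, nb), 1 + z_post * 0.1),
                 baseline_mean = 1, baseline_sd = 0.1,
                 z = c(rep(0, nb), z_post), n_events = 12,
                 degenerate = FALSE),
            class = "zpsth")
}

# A spike train with spikes at given times over [0, t_stop].
make_train <- function(times, t_stop, id = "u1")
  spike_train(id, sort(times), 0, t_stop)

# Regularly spaced events with full pre-onset baseline.
make_events <- function(n = 12, start = 10, gap = 40, dur = 30,
                        phase = "reward", label = "food_cue")
  event_series(label, start + (0:(n - 1)) * gap, dur, phase, TRUE)

# A stationary pose track (constant coordinates, optional jitter).
make_static_pose <- function(n_frames, frame_rate = 30, jitter = 0,
                             center = c(300, 130), seed = 1) {
  set.seed(seed)
  parts <- c("nose", "left_ear", "right_ear", "head_center", "spine",
             "tail_base")
  offx <- c(45, 22, 22, 28, 0, -42)
  x <- outer(rep(center[1], n_frames), offx, `+`) +
    matrix(stats::rnorm(n_frames * 6, 0, jitter), n_frames)
  y <- matrix(center[2], n_frames, 6) +
    matrix(stats::rnorm(n_frames * 6, 0, jitter), n_frames)
  colnames(x) <- colnames(y) <- parts
  lik <- matrix(0.99, n_frames, 6, dimnames = list(NULL, parts))
  pose_track((seq_len(n_frames) - 1) / frame_rate, frame_rate, x, y, lik)
}

# Overlap fraction between a detected bout and a scripted one.
bout_overlap <- function(det_on, det_dur, scr_on, scr_dur) {
  lo <- max(det_on, scr_on)
  hi <- min(det_on + det_dur, scr_on + scr_dur)
  max(hi - lo, 0) / scr_dur
}

empty_script <- data.frame(type = character(), onset = numeric(),
                           duration = numeric())
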