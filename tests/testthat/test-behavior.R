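# Pose-based behavior detection and phenotyping.

test_that("a stationary second becomes one freezing bout; 500 ms does not", {
  fr <- 30
  p <- make_static_pose(200, jitter = 0.1, seed = 2)
  # inject movement everywhere except frames 60..90 (one second still)
  set.seed(3)
  move <- matrix(stats::rnorm(200 * 6, 0, 4), 200)
  move[60:90, ] <- 0
  p$x <- p$x + apply(move, 2, cumsum)
  p$y <- p$y + apply(move, 2, cumsum)
  b <- detect_freezing(p)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 1, tolerance = 0.1)
  expect_equal(b$onset_s, 59 / fr, tolerance = 2 / fr)

  # exactly 15 still transitions = 500 ms: strict inequality drops it
  move2 <- matrix(stats::rnorm(200 * 6, 0, 4), 200)
  move2[60:74, ] <- 0
  p2 <- make_static_pose(200, jitter = 0.1, seed = 2)
  p2$x <- p2$x + apply(move2, 2, cumsum)
  p2$y <- p2$y + apply(move2, 2, cumsum)
  expect_equal(nrow(detect_freezing(p2)), 0)
})

test_that("random-walk jitter above tolerance never freezes", {
  zero <- vapply(1:20, function(s)
    nrow(detect_freezing(gen_pose(empty_script, duration = 30,
                                  seed = 40 + s))),
    numeric(1))
  expect_gte(mean(zero == 0), 0.95)
})

test_that("scripted bouts are recovered with >= 90% overlap", {
  script <- data.frame(type = c("freezing", "avoidance", "risk_assessment",
                                "freezing"),
                       onset = c(8, 20, 35, 48),
                       duration = c(2, 3, 2.5, 4))
  ar <- default_arena()
  for (s in 1:5) {
    p <- gen_pose(script, ar, duration = 60, seed = 80 + s)
    det <- rbind(detect_freezing(p), detect_avoidance(p, ar),
                 detect_risk_assessment(p, ar))
    for (k in seq_len(nrow(script))) {
      same <- det[det$type == script$type[k], ]
      ov <- vapply(seq_len(nrow(same)), function(j)
        bout_overlap(same$onset_s[j], same$duration_s[j],
                     script$onset[k], script$duration[k]), numeric(1))
      expect_gte(max(c(ov, 0)), 0.9)
    }
  }
})

test_that("zone membership is closed on the boundary", {
  p <- make_static_pose(30, center = c(300, 130))
  ar <- default_arena()
  p$x[, "head_center"] <- 200 # exactly on the hidden-zone edge
  p$y[, "head_center"] <- 100
  b <- detect_avoidance(p, ar)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 1)
  p$x[, "head_center"] <- 200.01
  expect_equal(nrow(detect_avoidance(p, ar)), 0)
})

test_that("unstretched hidden posture and stretched open posture are not risk assessment", {
  ar <- default_arena()
  hidden_only <- gen_pose(data.frame(type = "avoidance", onset = 5,
                                     duration = 4),
                          ar, duration = 30, seed = 7)
  expect_equal(nrow(detect_risk_assessment(hidden_only, ar)), 0)
  # stretched but fully in the open area
  p <- make_static_pose(120, jitter = 1, center = c(350, 130), seed = 8)
  p$x[40:70, "nose"] <- p$x[40:70, "nose"] + 60 # elongate in the open
  expect_equal(nrow(detect_risk_assessment(p, ar)), 0)
})

test_that("onset filtering enforces duration and the 6-s same-type baseline", {
  cfg <- analysis_config()
  b <- bouts <- data.frame(type = "freezing", onset_s = c(10, 13),
                           duration_s = c(2, 2))
  kept <- filter_onsets(b, cfg)
  expect_equal(kept$onset_s, 10)
  expect_equal(nrow(filter_onsets(
    data.frame(type = "freezing", onset_s = 5, duration_s = 0.8), cfg)), 0)
  both <- filter_onsets(data.frame(type = "freezing", onset_s = c(10, 20),
                                   duration_s = c(2, 2)), cfg)
  expect_equal(both$onset_s, c(10, 20))
  # different types do not shadow each other
  mixed <- filter_onsets(data.frame(type = c("freezing", "avoidance"),
                                    onset_s = c(10, 13),
                                    duration_s = c(2, 2)), cfg)
  expect_equal(nrow(mixed), 2)
})

test_that("onset filtering returns a subset and is idempotent", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    b <- data.frame(type = sample(c("freezing", "avoidance"), n, TRUE),
                    onset_s = sort(stats::runif(n, 0, 120)),
                    duration_s = stats::rexp(n, 0.5))
    k1 <- filter_onsets(b)
    expect_true(all(k1$onset_s %in% b$onset_s))
    k2 <- filter_onsets(cbind(k1, duration_s =
      b$duration_s[match(k1$onset_s, b$onset_s)]))
    expect_equal(k2$onset_s, k1$onset_s)
  }
})

test_that("behavior-aligned classification detects post-onset rate changes", {
  onsets <- seq(50, 490, by = 40)
  ev <- event_series("behavior_onset", onsets, 0, "odor")
  up <- gen_unit(unit_spec(10, "excited_sustained", response_gain = 3,
                           response_duration = 0.5), ev, 520, seed = 21)
  a <- align_responses_to_behavior(up, onsets)
  expect_equal(a$classification, "responds_after")
  expect_equal(a$direction, "excited")

  # 12 fine bins tested at z_excite/z_inhibit give a ~15-20% family-wise
  # false-positive rate by construction; demand no more than that
  flat <- vapply(1:20, function(s) {
    u <- gen_unit(unit_spec(8), duration = 520, seed = 500 + s)
    align_responses_to_behavior(u, onsets)$classification
  }, character(1))
  expect_gte(mean(flat == "none"), 0.75)
})

test_that("fewer than six usable onsets excludes the unit with a warning", {
  u <- gen_unit(unit_spec(5), duration = 200, seed = 5)
  expect_warning(a <- align_responses_to_behavior(u, seq(20, 180, by = 40)),
                 "excluded")
  expect_equal(a$classification, "excluded")
  # onsets without enough pre-onset time do not count as usable
  expect_warning(b <- align_responses_to_behavior(
    u, c(2, 3, 4, 5, 6, 50, 90, 130)), "excluded")
})

test_that("phenotype classification follows the binary conflict-press rule", {
  co <- gen_cohort(cohort_spec(n_sessions = 10, n_units = 1), seed = 17)
  got <- vapply(co$sessions, classify_phenotype, character(1))
  expect_equal(got, co$ground_truth$subjects$phenotype,
               ignore_attr = TRUE)

  s <- co$sessions[[which(got == "presser")[1]]]
  # strip conflict presses -> non_presser ("complete suppression")
  s$events <- lapply(s$events, function(es) {
    if (es$label != "lever_press") return(es)
    keep <- es$phase != "conflict"
    event_series("lever_press", es$onsets[keep], es$durations[keep],
                 es$phase[keep], es$rewarded[keep])
  })
  expect_equal(classify_phenotype(s), "non_presser")
  s$phase_intervals$conflict <- NULL
  expect_error(classify_phenotype(s), "conflict")
})

test_that("bout detection is invariant to uniform pixel translation", {
  script <- data.frame(type = c("freezing", "risk_assessment"),
                       onset = c(8, 20), duration = c(2, 3))
  ar <- default_arena()
  p <- gen_pose(script, ar, duration = 35, seed = 33)
  shift <- c(57, -23)
  p2 <- p
  p2$x <- p$x + shift[1]
  p2$y <- p$y + shift[2]
  ar2 <- arena_layout(lapply(ar$zones, function(z)
    z + c(shift[1], shift[1], shift[2], shift[2])),
    ar$slot + rep(shift, each = 2))
  expect_equal(detect_freezing(p), detect_freezing(p2))
  expect_equal(detect_risk_assessment(p, ar),
               detect_risk_assessment(p2, ar2))
  expect_equal(detect_avoidance(p, ar), detect_avoidance(p2, ar2))
})

test_that("frame-rate doubling by interpolation moves bout edges < 1 frame", {
  script <- data.frame(type = "avoidance", onset = 10, duration = 4)
  ar <- default_arena()
  p <- gen_pose(script, ar, duration = 25, seed = 44)
  n <- nrow(p$x)
  t2 <- seq(p$frame_times[1], p$frame_times[n], by = 1 / 60)
  interp <- function(m) apply(m, 2, function(v)
    stats::approx(p$frame_times, v, xout = t2)$y)
  p2 <- pose_track(t2, 60, interp(p$x), interp(p$y),
                   matrix(0.99, length(t2), 6,
                          dimnames = list(NULL, colnames(p$x))))
  b1 <- detect_avoidance(p, ar)
  b2 <- detect_avoidance(p2, ar)
  expect_equal(nrow(b1), nrow(b2))
  expect_lt(max(abs(b1$onset_s - b2$onset_s)), 1 / 30)
  expect_lt(max(abs(b1$duration_s - b2$duration_s)), 2 / 30)
})

test_that("masked gaps interpolate up to 0.5 s and break bouts beyond", {
  p <- make_static_pose(200, jitter = 0.05, seed = 9)
  set.seed(10)
  mv <- matrix(stats::rnorm(200 * 6, 0, 4), 200)
  mv[50:140, ] <- 0 # 3-s stillness
  p$x <- p$x + apply(mv, 2, cumsum)
  p$y <- p$y + apply(mv, 2, cumsum)
  p$x[80:85, "nose"] <- NA # 0.2-s gap: bridged
  b <- detect_freezing(p)
  expect_equal(nrow(b), 1)
  expect_gt(b$duration_s, 2.5)
  p$x[90:130, "spine"] <- NA # 1.3-s gap: breaks the run
  b2 <- detect_freezing(p)
  expect_true(all(b2$duration_s < 2))
})
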