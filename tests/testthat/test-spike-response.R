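# Z-scored PSTHs and the response classification rules.

test_that("Z values match a brute-force per-event recomputation exactly", {
  set.seed(42)
  for (rep in 1:10) {
    rate <- stats::runif(1, 2, 10)
    ev <- make_events(n = sample(4:12, 1), gap = stats::runif(1, 35, 45))
    u <- gen_unit(unit_spec(rate, sample(c("none", "excited_sustained"), 1)),
                  ev, 520, seed = 4000 + rep)
    p <- compute_zpsth(u, ev)
    expect_equal(p$z, oracle_zpsth_z(u, ev), tolerance = 1e-12)
  }
})

test_that("a gain-3 sustained response crosses threshold in the first bin", {
  ev <- make_events()
  hits <- vapply(1:20, function(s) {
    u <- gen_unit(unit_spec(5, "excited_sustained", response_gain = 3,
                            response_duration = 1.2), ev, 520, seed = 700 + s)
    p <- compute_zpsth(u, ev)
    r <- classify_event_response(p)
    p$z[21] > 2.58 && r$direction == "excited" && r$profile == "sustained"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("classification rules follow the first-two-bin thresholds", {
  cfg <- analysis_config()
  cfg_both <- analysis_config(detection_rule = "both_of_first_two_bins")
  z_rest <- rep(0, 8)
  expect_equal(classify_event_response(make_zpsth(c(3.0, 0.1, z_rest)),
                                       cfg)$direction, "excited")
  expect_equal(classify_event_response(make_zpsth(c(-2.5, -2.1, z_rest)),
                                       cfg)$direction, "inhibited")
  expect_equal(classify_event_response(make_zpsth(c(2.0, -1.5, z_rest)),
                                       cfg)$direction, "none")
  # strict variant requires the crossing in both bins
  expect_equal(classify_event_response(make_zpsth(c(3.0, 0.1, z_rest)),
                                       cfg_both)$direction, "none")
  expect_equal(classify_event_response(make_zpsth(c(3.0, 2.9, z_rest)),
                                       cfg_both)$direction, "excited")
  # excitation precedence across the two bins
  expect_equal(classify_event_response(make_zpsth(c(3.0, -2.5, z_rest)),
                                       cfg)$direction, "excited")
})

test_that("temporal profile splits transient, intermediate and sustained", {
  one <- make_zpsth(c(3, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  two <- make_zpsth(c(3, 3, 0, 0, 0, 0, 0, 0, 0, 0))
  four <- make_zpsth(c(3, 3, 3, 3, 0, 0, 0, 0, 0, 0))
  expect_equal(classify_event_response(one)$profile, "transient")
  expect_equal(classify_event_response(two)$profile, "intermediate")
  expect_equal(classify_event_response(four)$profile, "sustained")
  # a run must intersect the first two bins: late bins alone do not count
  late <- make_zpsth(c(3, 0, 0, 3, 3, 3, 3, 0, 0, 0))
  expect_equal(classify_event_response(late)$profile, "transient")
  # profile is undefined for non-excited responses
  r <- classify_event_response(make_zpsth(rep(0, 10)))
  expect_equal(r$profile, "na")
  expect_error(classify_temporal_profile(make_zpsth(rep(0, 10)), r),
               "excited")
})

test_that("signed AUC matches hand computation and is additive", {
  p <- make_zpsth(c(2, 1, -1, 0, rep(0, 6)))
  expect_equal(response_auc(p, "positive"), 0.9)
  expect_equal(response_auc(p, "negative"), -0.3)
  p0 <- make_zpsth(rep(0, 10))
  expect_equal(response_auc(p0, "positive"), 0)
  expect_equal(response_auc(p0, "negative"), 0)
  set.seed(1)
  for (i in 1:20) {
    z <- stats::rnorm(10, 0, 2)
    p <- make_zpsth(z)
    expect_equal(response_auc(p, "positive") + response_auc(p, "negative"),
                 0.3 * sum(z), tolerance = 1e-12)
  }
})

test_that("a zero-spike unit takes the degenerate-baseline path with Z = 0", {
  u <- make_train(numeric(0), 600)
  p <- compute_zpsth(u, make_events())
  expect_true(all(p$z == 0))
  expect_false(p$degenerate)
  expect_equal(p$baseline_sd, 0)
})

test_that("preconditions are enforced with informative errors", {
  u <- gen_unit(unit_spec(5), duration = 100, seed = 1)
  expect_error(compute_zpsth(u, event_series("food_cue", 50, 30, "reward")),
               ">= 2 events")
  early <- event_series("food_cue", c(2, 50), 30, "reward")
  expect_error(compute_zpsth(u, early), "2")
})

test_that("classification is invariant to uniform time translation", {
  ev <- make_events()
  u <- gen_unit(unit_spec(5, "excited_transient"), ev, 520, seed = 77)
  r1 <- classify_event_response(compute_zpsth(u, ev))
  shift <- 345.6
  u2 <- make_train(u$spike_times + shift, 520 + shift)
  ev2 <- event_series("food_cue", ev$onsets + shift, ev$durations, ev$phase,
                      ev$rewarded)
  u2$t_start <- shift
  r2 <- classify_event_response(compute_zpsth(u2, ev2))
  r2$unit_id <- r1$unit_id
  expect_equal(r1, r2)
})

test_that("spontaneous-rate comparison has power and holds its level", {
  cfg <- analysis_config()
  base_win <- c(0, 30)
  phase_win <- c(40, 70)
  calls <- function(rate_phase, n = 60, from = 0) vapply(1:n, function(s) {
    u1 <- gen_unit(unit_spec(5), duration = 35, seed = from + 2 * s)
    u2 <- gen_unit(unit_spec(rate_phase), duration = 35, seed = from + 2 * s + 1)
    u <- make_train(c(u1$spike_times, u2$spike_times + 35), 70)
    classify_spontaneous_change(u, c(0, 30), c(38, 68), cfg)
  }, character(1))
  null <- calls(5, from = 10000)
  expect_gte(mean(null == "none"), 0.85)
  up <- calls(15, from = 20000)
  expect_gte(mean(up == "excited"), 0.95)
  down <- calls(1, from = 30000)
  expect_gte(mean(down == "inhibited"), 0.9)
  expect_error(classify_spontaneous_change(
    gen_unit(unit_spec(5), duration = 50, seed = 1), c(0, 30), c(30, 60)),
    "outside")
})

test_that("phase tracking tabulates transitions and excludes missing units", {
  rec <- data.frame(unit_id = rep(c("a", "b", "c"), 2),
                    phase = rep(c("reward", "conflict"), each = 3),
                    direction = c("excited", "none", "inhibited",
                                  "none", "none", "inhibited"))
  tr <- track_across_phases(rec, phases = c("reward", "conflict"))
  tt <- tr$transitions[["reward->conflict"]]
  expect_equal(unname(tt["excited", "none"]), 1)
  expect_equal(unname(tt["none", "none"]), 1)
  expect_equal(unname(tt["inhibited", "inhibited"]), 1)
  expect_equal(sum(tt), 3)
  m <- tr$marginals
  expect_equal(m$n[m$phase == "reward" & m$direction == "excited"], 1)

  rec2 <- rec[-4, ] # unit "a" missing in conflict
  expect_warning(tr2 <- track_across_phases(rec2,
                                            phases = c("reward", "conflict")),
                 "a")
  expect_equal(nrow(tr2$per_unit), 2)

  empty <- track_across_phases(rec[0, ])
  expect_equal(nrow(empty$per_unit), 0)
})

test_that("planted reward-phase responder fraction is recovered in a cohort", {
  co <- gen_cohort(cohort_spec(n_sessions = 6, n_units = 6), seed = 14)
  cfg <- analysis_config()
  got <- planted <- 0; n <- 0
  for (i in seq_along(co$sessions)) {
    s <- co$sessions[[i]]
    cues <- s$events[[1]]
    sel <- cues$phase == "reward"
    ev <- event_series("food_cue", cues$onsets[sel], cues$durations[sel],
                       "reward", cues$rewarded[sel])
    for (u in s$units) {
      r <- classify_event_response(compute_zpsth(u, ev, cfg), cfg)
      got <- got + (r$direction != "none")
      n <- n + 1
    }
  }
  planted <- sum(co$ground_truth$units$response_kind != "none")
  # recovered count within a binomial CI of the plant (plus ~9% chance level)
  expect_gt(got, planted - 3 * sqrt(n * 0.33 * 0.67))
  expect_lt(got, planted + 0.1 * n + 3 * sqrt(n * 0.4))
})
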