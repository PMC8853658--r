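# Session containers, validation and manifest I/O.

test_that("a saved session reloads field-by-field", {
  co <- gen_cohort(cohort_spec(n_sessions = 1, n_units = 3,
                               include_pose = TRUE, include_lfp = TRUE,
                               lfp_duration = 12, lfp_fs = 250), seed = 4)
  s <- co$sessions[[1]]
  root <- withr::local_tempdir()
  save_session(s, root)
  s2 <- load_session(root)
  expect_equal(s2$subject_id, s$subject_id)
  expect_equal(s2$phenotype, s$phenotype)
  expect_equal(s2$phase_intervals, s$phase_intervals)
  expect_equal(s2$units, s$units)
  expect_equal(s2$lfp$samples, s$lfp$samples)
  expect_equal(s2$lfp$fs, s$lfp$fs)
  expect_equal(s2$pose$x, s$pose$x)
  expect_equal(s2$pose$likelihood, s$pose$likelihood)
  expect_equal(s2$arena$zones, s$arena$zones)
  ev1 <- s$events[[which(sapply(s$events, `[[`, "label") == "food_cue")]]
  ev2 <- s2$events[[which(sapply(s2$events, `[[`, "label") == "food_cue")]]
  expect_equal(ev1$onsets, ev2$onsets)
  expect_equal(ev1$phase, ev2$phase)
  expect_equal(ev1$rewarded, ev2$rewarded)
  expect_length(validate_session(s2), 0)
})

test_that("a spike file with a timestamp beyond t_stop fails naming the unit", {
  co <- gen_cohort(cohort_spec(n_sessions = 1, n_units = 2), seed = 5)
  root <- withr::local_tempdir()
  save_session(co$sessions[[1]], root)
  f <- file.path(root, "spikes", paste0(co$sessions[[1]]$units[[2]]$unit_id,
                                        ".csv"))
  df <- utils::read.csv(f)
  df <- rbind(df, data.frame(t_s = co$sessions[[1]]$t_stop + 100))
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(load_session(root), co$sessions[[1]]$units[[2]]$unit_id)
})

test_that("a missing manifest is a hard error", {
  expect_error(load_session(withr::local_tempdir()), "manifest")
})

test_that("DLC-dialect pose CSV round-trips with 3 header rows", {
  p <- make_static_pose(100, jitter = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  conflictephys:::write_dlc_csv(p, f)
  expect_length(readLines(f), 103) # 3 header rows + 100 frames
  p2 <- read_dlc_csv(f, frame_rate = 30)
  expect_equal(ncol(p2$x), 6)
  expect_equal(nrow(p2$x), 100)
  expect_equal(sort(colnames(p2$x)),
               sort(c("nose", "left_ear", "right_ear", "head_center",
                      "spine", "tail_base")))
  expect_equal(p2$x, p$x, tolerance = 1e-12)
})

test_that("a pose CSV with an unknown body part is rejected", {
  p <- make_static_pose(10)
  f <- withr::local_tempfile(fileext = ".csv")
  conflictephys:::write_dlc_csv(p, f)
  txt <- readLines(f)
  txt[2] <- gsub("spine", "whisker", txt[2])
  writeLines(txt, f)
  expect_error(read_dlc_csv(f), "whisker")
})

test_that("low-likelihood pose frames are masked on load", {
  co <- gen_cohort(cohort_spec(n_sessions = 1, n_units = 1), seed = 11)
  s <- co$sessions[[1]]
  s$pose <- make_static_pose(50)
  s$pose$likelihood[10:12, "nose"] <- 0.2
  root <- withr::local_tempdir()
  save_session(s, root)
  s2 <- load_session(root)
  expect_true(all(is.na(s2$pose$x[10:12, "nose"])))
  expect_false(anyNA(s2$pose$x[-(10:12), ]))
})

test_that("validate_session reports exactly the injected violation", {
  co <- gen_cohort(cohort_spec(n_sessions = 1, n_units = 2), seed = 6)
  s <- co$sessions[[1]]
  expect_length(validate_session(s), 0)

  bad <- s
  bad$phase_intervals$odor <- c(bad$phase_intervals$reward[1] + 1,
                                bad$phase_intervals$reward[2] + 1)
  v <- validate_session(bad)
  expect_length(v, 1)
  expect_match(v, "phase_intervals")

  bad <- s
  bad$units[[1]]$spike_times <- rev(bad$units[[1]]$spike_times)
  v <- validate_session(bad)
  expect_match(v, bad$units[[1]]$unit_id)
  expect_match(v, "increasing")

  bad <- s
  bad$events[[1]]$onsets[1] <- s$t_stop + 50
  v <- validate_session(bad)
  expect_true(any(grepl("outside recording bounds", v)))

  bad <- s
  bad$pose <- make_static_pose(20)
  bad$pose$likelihood[3, 2] <- 1.7
  expect_true(any(grepl("likelihood", validate_session(bad))))
})

test_that("save_results writes one CSV per table plus a manifest", {
  out <- withr::local_tempdir()
  tabs <- list(alpha = data.frame(a = 1:3, b = c("x", "y", "z")),
               beta = data.frame(v = c(0.5, 0.25)))
  man <- save_results(tabs, out, analysis_config(rng_seed = 7))
  expect_setequal(list.files(out),
                  c("alpha.csv", "beta.csv", "run_manifest.json"))
  expect_equal(man$seed, 7)
  expect_equal(utils::read.csv(file.path(out, "alpha.csv"))$a, 1:3)
})

test_that("an empty table set yields a manifest only", {
  out <- withr::local_tempdir()
  save_results(list(), out)
  expect_equal(list.files(out), "run_manifest.json")
})

test_that("re-running save_results is byte-identical", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  tab <- list(t = data.frame(x = stats::rnorm(5)))
  save_results(tab, out1, analysis_config())
  save_results(tab, out2, analysis_config())
  expect_identical(readLines(file.path(out1, "t.csv")),
                   readLines(file.path(out2, "t.csv")))
})

test_that("analysis_config rejects degenerate parameters", {
  expect_error(analysis_config(psth_bin = 0), "psth_bin")
  expect_error(analysis_config(bands = list(delta = c(0, 5),
                                            theta = c(4, 10))),
               "non-overlapping")
  expect_error(analysis_config(n_baseline_bins = 1), "n_baseline_bins")
})

test_that("config YAML round-trips including the detection rule", {
  f <- withr::local_tempfile(fileext = ".yaml")
  cfg <- analysis_config(detection_rule = "both_of_first_two_bins",
                         z_excite = 3.0, rng_seed = 42)
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2, cfg)
})
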