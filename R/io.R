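# Manifest-based session directory layout. One `session.json` names every
# file; spikes are one CSV per unit (column t_s), events a single CSV, pose a
# DeepLabCut-dialect CSV (3 header rows), LFP a one-column CSV with its rate
# in the manifest, arena a JSON of zone rectangles plus slot endpoints.

#' Write a session to a directory
#'
#' @param s a [session].
#' @param root directory to create/populate.
#' @return `root`, invisibly.
#' @export
save_session <- function(s, root) {
  dir.create(file.path(root, "spikes"), recursive = TRUE, showWarnings = FALSE)
  man <- list(subject_id = s$subject_id, phenotype = s$phenotype,
              t_start = s$t_start, t_stop = s$t_stop,
              phase_intervals = s$phase_intervals,
              units = lapply(s$units, function(u)
                list(unit_id = u$unit_id, t_start = u$t_start,
                     t_stop = u$t_stop,
                     file = file.path("spikes", paste0(u$unit_id, ".csv")))),
              files = list(events = "events.csv"))
  for (u in s$units)
    utils::write.csv(data.frame(t_s = u$spike_times),
                     file.path(root, "spikes", paste0(u$unit_id, ".csv")),
                     row.names = FALSE)
  ev <- do.call(rbind, lapply(s$events, function(es)
    data.frame(label = es$label, onset_s = es$onsets,
               duration_s = es$durations, phase = es$phase,
               rewarded = es$rewarded,
               train = if (is.null(es$train)) NA_integer_ else es$train)))
  if (is.null(ev))
    ev <- data.frame(label = character(), onset_s = numeric(),
                     duration_s = numeric(), phase = character(),
                     rewarded = logical(), train = integer())
  utils::write.csv(ev, file.path(root, "events.csv"), row.names = FALSE)
  if (!is.null(s$pose)) {
    write_dlc_csv(s$pose, file.path(root, "pose.csv"))
    man$files$pose <- "pose.csv"
    man$frame_rate <- s$pose$frame_rate
  }
  if (!is.null(s$lfp)) {
    utils::write.csv(data.frame(uv = s$lfp$samples),
                     file.path(root, "lfp.csv"), row.names = FALSE)
    man$files$lfp <- "lfp.csv"
    man$lfp <- list(fs = s$lfp$fs, t_start = s$lfp$t_start)
  }
  if (!is.null(s$arena)) {
    jsonlite::write_json(list(zones = s$arena$zones,
                              slot = unclass(as.data.frame(s$arena$slot))),
                         file.path(root, "arena.json"), auto_unbox = TRUE,
                         digits = NA)
    man$files$arena <- "arena.json"
  }
  jsonlite::write_json(man, file.path(root, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(root)
}

#' Load a session directory
#'
#' Reads the `session.json` manifest and every referenced file, validates all
#' invariants (any violation is a hard error naming the offender), and masks
#' pose frames whose likelihood falls below `config$likelihood_cutoff`.
#'
#' @param root session directory containing `session.json`.
#' @param config an [analysis_config].
#' @return a validated [session].
#' @export
load_session <- function(root, config = analysis_config()) {
  mf <- file.path(root, "session.json")
  if (!file.exists(mf)) stopf("missing session manifest: %s", mf)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  units <- lapply(man$units, function(u) {
    df <- utils::read.csv(file.path(root, u$file))
    spike_train(u$unit_id, df$t_s, u$t_start, u$t_stop)
  })
  ev <- utils::read.csv(file.path(root, man$files$events),
                        stringsAsFactors = FALSE)
  events <- lapply(split(seq_len(nrow(ev)), factor(ev$label)), function(i) {
    tr <- ev$train[i]
    event_series(ev$label[i[1]], ev$onset_s[i], ev$duration_s[i],
                 ev$phase[i], ev$rewarded[i],
                 train = if (!all(is.na(tr))) tr)
  })
  names(events) <- NULL
  pose <- NULL
  if (!is.null(man$files$pose)) {
    pose <- read_dlc_csv(file.path(root, man$files$pose),
                         frame_rate = man$frame_rate %||% config$frame_rate)
    mask <- pose$likelihood < config$likelihood_cutoff
    pose$x[mask] <- NA_real_
    pose$y[mask] <- NA_real_
  }
  lfp <- NULL
  if (!is.null(man$files$lfp)) {
    sm <- utils::read.csv(file.path(root, man$files$lfp))
    lfp <- lfp_signal(sm$uv, man$lfp$fs, man$lfp$t_start %||% 0)
  }
  arena <- NULL
  if (!is.null(man$files$arena)) {
    aj <- jsonlite::read_json(file.path(root, man$files$arena),
                              simplifyVector = TRUE)
    arena <- arena_layout(aj$zones, as.matrix(as.data.frame(aj$slot)))
  }
  session(man$subject_id, man$phase_intervals, units = units,
          events = events, phenotype = man$phenotype %||% "unknown",
          pose = pose, lfp = lfp, arena = arena,
          t_start = man$t_start, t_stop = man$t_stop)
}

# DeepLabCut CSV dialect: 3 header rows (scorer / bodyparts / coords), first
# column the frame index, then x,y,likelihood triplets per body part.
write_dlc_csv <- function(pose, path) {
  parts <- colnames(pose$x)
  hdr1 <- c("scorer", rep("synthetic", 3 * length(parts)))
  hdr2 <- c("bodyparts", rep(parts, each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  n <- nrow(pose$x)
  body <- matrix(0, n, 3 * length(parts))
  for (j in seq_along(parts)) {
    body[, 3 * j - 2] <- pose$x[, j]
    body[, 3 * j - 1] <- pose$y[, j]
    body[, 3 * j] <- pose$likelihood[, j]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  utils::write.table(cbind(seq_len(n) - 1L, body), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DeepLabCut-dialect pose CSV
#'
#' Expects the standard three header rows (scorer, bodyparts, coords) with
#' x, y, likelihood triplets per body part. Unknown body parts are an error.
#'
#' @param path CSV path.
#' @param frame_rate frame rate in Hz used to construct frame times.
#' @return a [pose_track].
#' @export
read_dlc_csv <- function(path, frame_rate = 30) {
  hdr <- readLines(path, n = 3)
  bodyparts <- strsplit(hdr[2], ",")[[1]][-1]
  coords <- strsplit(hdr[3], ",")[[1]][-1]
  parts <- unique(bodyparts)
  bad <- setdiff(parts, POSE_PARTS)
  if (length(bad)) stopf("unknown body part(s) in pose file: %s",
                         paste(bad, collapse = ", "))
  df <- utils::read.csv(path, skip = 3, header = FALSE)
  n <- nrow(df)
  mk <- function(coord) {
    m <- matrix(NA_real_, n, length(parts), dimnames = list(NULL, parts))
    for (p in parts) {
      j <- which(bodyparts == p & coords == coord) + 1L # +1: frame col
      m[, p] <- df[[j]]
    }
    m
  }
  pose_track(frame_times = (seq_len(n) - 1L) / frame_rate,
             frame_rate = frame_rate,
             x = mk("x"), y = mk("y"), likelihood = mk("likelihood"))
}

#' Write result tables and a run manifest
#'
#' Each table becomes `<name>.csv` with deterministic column order (as given);
#' the manifest `run_manifest.json` echoes the configuration, seed and package
#' version so a run can be reproduced. Re-running with identical inputs and
#' seed produces byte-identical CSVs.
#'
#' @param tables named list of data.frames (may be empty).
#' @param out output directory (created if needed).
#' @param config optional [analysis_config] echoed into the manifest.
#' @return invisibly, the manifest as a list.
#' @export
save_results <- function(tables, out, config = NULL) {
  if (length(tables) && is.null(names(tables)))
    stopf("result tables must be named")
  ok <- dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stopf("cannot create output directory %s", out)
  files <- character()
  for (nm in names(tables)) {
    f <- file.path(out, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files[nm] <- basename(f)
  }
  man <- list(files = as.list(files),
              n_tables = length(tables),
              seed = if (!is.null(config)) config$rng_seed,
              config = if (!is.null(config)) unclass(config),
              package_version = as.character(utils::packageVersion("conflictephys")))
  jsonlite::write_json(man, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(man)
}
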