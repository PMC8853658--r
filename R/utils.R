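# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic counter-based fan-out so that per-session and per-unit
#' randomness is reproducible for any subset of a cohort. Keeps results in
#' the 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param ... integer counters (e.g. session index, unit index).
#' @return an integer seed.
#' @export
child_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1
  s <- as.numeric(seed) %% m
  for (k in idx) {
    s <- (s * 48271 + as.numeric(k) * 16807 + 1) %% m
  }
  as.integer(s)
}

# Spike counts in half-open windows [starts, starts + width).
# left.open makes findInterval count spikes strictly below the edge, so a
# spike exactly on an edge belongs to the bin it starts.
count_in_windows <- function(spike_times, starts, width) {
  findInterval(starts + width, spike_times, left.open = TRUE) -
    findInterval(starts, spike_times, left.open = TRUE)
}

# Trial-averaged counts per bin: events x bins matrix collapsed to bin means.
# edges are offsets relative to each onset; bins are half-open [e_i, e_{i+1}).
mean_counts_by_bin <- function(spike_times, onsets, edges) {
  nb <- length(edges) - 1L
  tot <- numeric(nb)
  for (on in onsets) {
    idx <- findInterval(on + edges, spike_times, left.open = TRUE)
    tot <- tot + diff(idx)
  }
  tot / length(onsets)
}

# Population (n-denominator) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Maximal runs of TRUE in a logical vector; returns start/end indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
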