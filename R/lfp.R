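# Power spectral density and band-fraction summaries. The estimator is
# Welch's averaged periodogram: 2-s Hann-tapered segments with 50% overlap
# give 0.5-Hz resolution, enough to resolve the 4-Hz delta/theta boundary.

# One-sided Hann-tapered periodogram of a segment, power per Hz.
segment_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n) # Hann
  xw <- (x - mean(x)) * w
  sp <- abs(stats::fft(xw))^2 / (fs * sum(w^2))
  nf <- floor(n / 2) + 1
  p <- sp[seq_len(nf)]
  # double everything except DC (and Nyquist for even n)
  dbl <- 2:(nf - if (n %% 2 == 0) 1 else 0)
  p[dbl] <- 2 * p[dbl]
  p
}

#' Welch power spectral density of a field potential
#'
#' Averaged one-sided periodogram over Hann-tapered segments
#' (`config$psd_segment` seconds, `config$psd_overlap` overlap), returned up
#' to 100 Hz.
#'
#' @param lfp an [lfp_signal].
#' @param window optional c(start, end) analysis window, seconds (must lie
#'   inside the recording and span at least 4 s).
#' @param config an [analysis_config].
#' @param fmax highest returned frequency, Hz.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
compute_psd <- function(lfp, window = NULL, config = analysis_config(),
                        fmax = 100) {
  x <- lfp$samples
  fs <- lfp$fs
  if (!is.null(window)) {
    t_end <- lfp$t_start + length(x) / fs
    if (window[1] < lfp$t_start || window[2] > t_end + 1e-9)
      stopf("window [%g, %g) outside recording", window[1], window[2])
    if (diff(window) < 4) stopf("analysis window must span >= 4 s")
    i0 <- floor((window[1] - lfp$t_start) * fs) + 1
    i1 <- floor((window[2] - lfp$t_start) * fs)
    x <- x[i0:i1]
  } else if (length(x) < 4 * fs) stopf("signal must span >= 4 s")
  nseg <- round(config$psd_segment * fs)
  hop <- max(1, round(nseg * (1 - config$psd_overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  acc <- 0
  for (s in starts) acc <- acc + segment_psd(x[s:(s + nseg - 1)], fs)
  psd <- acc / length(starts)
  freq <- seq(0, fs / 2, length.out = floor(nseg / 2) + 1)
  keep <- freq <= fmax
  list(freq = freq[keep], psd = psd[keep])
}

#' Band fractions of total 0-100 Hz power
#'
#' Integrates the PSD over each configured band (half-open `[lo, hi)`
#' intervals over the frequency grid; the last band is closed above) and
#' expresses each as a percentage of the total 0-100 Hz power, so the
#' fractions of a full band partition sum to 100.
#'
#' @param freq,psd as returned by [compute_psd].
#' @param bands named list of c(lo, hi) band edges, Hz.
#' @return object of class `band_summary`: named percentage vector.
#' @export
band_fractions <- function(freq, psd,
                           bands = analysis_config()$bands) {
  hi_all <- max(vapply(bands, `[`, numeric(1), 2))
  if (hi_all > max(freq) + 1e-9)
    stopf("bands exceed the frequency support (max %g Hz)", max(freq))
  total <- sum(psd[freq <= hi_all])
  if (total <= 0) stopf("zero total power")
  last <- names(bands)[which.max(vapply(bands, `[`, numeric(1), 2))]
  out <- vapply(names(bands), function(nm) {
    b <- bands[[nm]]
    sel <- freq >= b[1] & (if (nm == last) freq <= b[2] else freq < b[2])
    100 * sum(psd[sel]) / total
  }, numeric(1))
  structure(out, class = "band_summary")
}

#' @export
print.band_summary <- function(x, ...) {
  cat("<band_summary> % of 0-100 Hz power\n")
  for (nm in names(x)) cat(sprintf("  %-6s %6.2f\n", nm, x[[nm]]))
  invisible(x)
}

#' Time-frequency map of log power
#'
#' Short-time transform with 2-s Hann windows and 50% overlap; values are
#' 10*log10(power/Hz) in dB re 1 unit^2/Hz.
#'
#' @param lfp an [lfp_signal] of at least 4 s.
#' @param config an [analysis_config].
#' @param fmax highest returned frequency, Hz.
#' @return object of class `spectrogram`: list with `time` (window centers,
#'   s), `freq` (Hz) and `db` (freq x time matrix).
#' @export
spectrogram_logpsd <- function(lfp, config = analysis_config(), fmax = 100) {
  x <- lfp$samples
  fs <- lfp$fs
  if (length(x) < 4 * fs) stopf("signal must span >= 4 s")
  nseg <- round(config$psd_segment * fs)
  hop <- max(1, round(nseg * (1 - config$psd_overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  freq <- seq(0, fs / 2, length.out = floor(nseg / 2) + 1)
  keep <- freq <= fmax
  m <- vapply(starts, function(s) segment_psd(x[s:(s + nseg - 1)], fs)[keep],
              numeric(sum(keep)))
  structure(list(time = lfp$t_start + (starts - 1 + nseg / 2) / fs,
                 freq = freq[keep],
                 db = 10 * log10(pmax(m, .Machine$double.xmin))),
            class = "spectrogram")
}

#' @export
plot.spectrogram <- function(x, ...) {
  graphics::image(x$time, x$freq, t(x$db), xlab = "time (s)",
                  ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Compare per-band PSD area between two groups
#'
#' For each session the PSD is normalized to percent of total 0-100 Hz power
#' and integrated over each band; bands are then compared between groups with
#' Welch's two-sample t-test.
#'
#' @param group_a,group_b lists of `list(freq, psd)` per session (each as
#'   returned by [compute_psd]); at least two sessions per group.
#' @param bands named list of band edges, Hz.
#' @return data.frame with one row per band: `band`, `mean_a`, `mean_b`,
#'   `mean_diff` (a - b), `t`, `p`.
#' @export
compare_band_auc <- function(group_a, group_b,
                             bands = analysis_config()$bands) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("each group needs >= 2 sessions")
  auc <- function(g) t(vapply(g, function(s)
    unclass(band_fractions(s$freq, s$psd, bands)),
    numeric(length(bands))))
  a <- auc(group_a)
  b <- auc(group_b)
  rows <- lapply(seq_along(bands), function(j) {
    tt <- stats::t.test(a[, j], b[, j]) # Welch by default
    data.frame(band = names(bands)[j], mean_a = mean(a[, j]),
               mean_b = mean(b[, j]),
               mean_diff = mean(a[, j]) - mean(b[, j]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, rows)
}
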