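# Morlet CWT and noise-adaptive footstep impulse detection.

#' Morlet continuous wavelet transform
#'
#' Complex Morlet CWT (centre-frequency parameter omega0 = 6) computed by FFT
#' convolution on a requested frequency grid. The scale-to-frequency mapping
#' uses the exact Fourier factor for the Morlet wavelet, so a pure tone's
#' magnitude peaks at the grid frequency nearest the tone.
#'
#' @param x numeric vector of samples (one channel).
#' @param sample_rate Hz.
#' @param freqs frequency grid in Hz, strictly inside (0, Nyquist).
#' @param times optional time axis (defaults to samples / sample_rate).
#' @param keep_complex keep the complex coefficients alongside the magnitude
#'   (memory-heavy; used by linearity checks).
#' @return an object of class `wavelet_spectrum`: list with `freq`, `time`,
#'   `magnitude` (freq x time matrix, >= 0) and optionally `coef`.
#' @export
morlet_cwt <- function(x, sample_rate, freqs, times = NULL,
                       keep_complex = FALSE) {
  if (length(freqs) == 0) stop("empty frequency grid", call. = FALSE)
  if (any(freqs <= 0) || any(freqs >= sample_rate / 2))
    stop_field("freqs", "must lie strictly inside (0, Nyquist)")
  n <- length(x)
  nfft <- nextn(2L * n, 2)
  X <- fft(c(x, numeric(nfft - n)))
  omega0 <- 6
  fourier_factor <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi) # s = ff / f
  dt <- 1 / sample_rate
  wk <- 2 * pi * (seq_len(nfft) - 1) / (nfft * dt)
  wk[wk > pi / dt] <- wk[wk > pi / dt] - 2 * pi / dt  # signed angular freqs
  pos <- wk > 0

  mag <- matrix(0, length(freqs), n)
  cf <- if (keep_complex) matrix(0i, length(freqs), n) else NULL
  for (i in seq_along(freqs)) {
    s <- fourier_factor / freqs[i]
    psi <- numeric(nfft)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * wk[pos] - omega0)^2 / 2)
    w <- fft(X * psi, inverse = TRUE)[seq_len(n)] / nfft
    mag[i, ] <- Mod(w)
    if (keep_complex) cf[i, ] <- w
  }
  structure(list(
    freq = freqs,
    time = times %||% ((seq_len(n) - 1) * dt),
    magnitude = mag,
    coef = cf
  ), class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d freqs (%.3g-%.3g Hz) x %d times\n",
              length(x$freq), min(x$freq), max(x$freq), length(x$time)))
  invisible(x)
}

#' Sum wavelet magnitudes over a frequency band
#'
#' Per-time sum of CWT magnitudes over all grid rows with
#' `f_lo <= f <= f_hi` (inclusive).
#'
#' @param spectrum a `wavelet_spectrum`.
#' @param f_lo,f_hi band edges in Hz; must intersect the grid.
#' @return numeric vector over the spectrum's time axis.
#' @export
band_sum <- function(spectrum, f_lo, f_hi) {
  rows <- which(spectrum$freq >= f_lo & spectrum$freq <= f_hi)
  if (length(rows) == 0)
    stop(sprintf("band [%g, %g] Hz does not intersect the frequency grid",
                 f_lo, f_hi), call. = FALSE)
  if (length(rows) == 1) spectrum$magnitude[rows, ]
  else colSums(spectrum$magnitude[rows, , drop = FALSE])
}

# Channel-summed band series used by detection: CWT each channel over
# `freqs`, band-sum, add channels, then smooth with a short moving average
# (default 80 ms) to stabilize peak prominences against noise excursions.
# Noise statistics are computed on the same smoothed construction.
detection_series <- function(record, band = c(5, 50), freqs = NULL,
                             smooth_s = 0.08) {
  freqs <- freqs %||% band_freq_grid(band, record$sample_rate)
  ids <- rec_sensors(record)
  tm <- rec_times(record)
  per <- matrix(0, nrow(record$samples), length(ids),
                dimnames = list(NULL, ids))
  for (ch in ids) {
    sp <- morlet_cwt(record$samples[, ch], record$sample_rate, freqs,
                     times = tm)
    per[, ch] <- band_sum(sp, band[1], band[2])
  }
  series <- rowSums(per)
  k <- max(1L, round(smooth_s * record$sample_rate))
  if (k > 1L) series <- moving_average(series, k)
  list(time = tm, series = series, per_channel = per)
}

# Centred moving average with shrinking windows at the edges.
moving_average <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Default analysis grid inside a band, ~2.5 Hz spacing, respecting Nyquist.
band_freq_grid <- function(band, fs, by = 2.5) {
  hi <- min(band[2], 0.45 * fs)
  seq(max(band[1], 1), hi, by = by)
}

#' Noise statistics of the band-summed wavelet series
#'
#' Mean and standard deviation of the channel-summed, band-summed wavelet
#' coefficient magnitude over a quiet (noise-only) interval. Detection
#' thresholds are expressed relative to these statistics so that the system
#' adapts to noise conditions and amplification settings.
#'
#' @param record a [vibration_record()].
#' @param quiet_interval `c(t0, t1)` in seconds, inside the record, at least
#'   0.2 s long (1 s or more recommended).
#' @param band frequency band in Hz (default the 5-50 Hz floor
#'   natural-frequency range).
#' @return an object of class `noise_stats`: list with `mean`, `sd`, `band`.
#' @export
estimate_noise_stats <- function(record, quiet_interval, band = c(5, 50)) {
  tm <- rec_times(record)
  if (quiet_interval[1] < tm[1] - 1e-9 ||
      quiet_interval[2] > tm[length(tm)] + 1e-9)
    stop("quiet interval lies outside the record", call. = FALSE)
  idx <- which(tm >= quiet_interval[1] & tm <= quiet_interval[2])
  if (length(idx) < 0.2 * record$sample_rate)
    stop("quiet interval must be at least 0.2 s long", call. = FALSE)
  sub <- vibration_record(record$samples[idx, , drop = FALSE],
                          record$sample_rate, start_time = tm[idx[1]])
  ds <- detection_series(sub, band)
  # trim CWT edge effects (one wavelet width at the band's low edge)
  guard <- min(floor(length(idx) / 4), ceiling(record$sample_rate / band[1]))
  core <- ds$series[(guard + 1):(length(ds$series) - guard)]
  structure(list(mean = mean(core), sd = sd(core), band = band),
            class = "noise_stats")
}

# Local maxima of a series with prominence. Returns data.frame(idx, height,
# prominence) sorted by index. Prominence: height minus the highest minimum
# that must be descended to reach a higher peak (or the series edge).
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(idx = integer(), height = numeric(),
                               prominence = numeric()))
  up <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(up) == 0) return(data.frame(idx = integer(), height = numeric(),
                                         prominence = numeric()))
  prom <- vapply(up, function(i) {
    h <- y[i]
    left <- y[seq_len(i)]
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(left[max(hi_l):i]) else min(left)
    right <- y[i:n]
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(right[1:min(hi_r)]) else min(right)
    h - max(base_l, base_r)
  }, 0)
  data.frame(idx = up, height = y[up], prominence = prom)
}

#' Detect individual footsteps
#'
#' Peak picking on the 5-50 Hz band-summed wavelet series (summed across
#' channels), with noise-adaptive thresholds: peak height above
#' `noise$mean + height_k * noise$sd`, prominence above
#' `prominence_k * noise$sd`, minimum peak separation `spacing_s[1]` (larger
#' peak kept), and only runs of at least `min_consecutive` peaks whose
#' spacing stays within `spacing_s` are retained — isolated impulses such as
#' item drops are rejected by that rule alone. Sides alternate A, B, A, ...
#' by parity; the per-event channel is the one with the largest band energy
#' at the peak.
#'
#' @param record a [vibration_record()] (already lowpassed if required).
#' @param noise a [estimate_noise_stats()] result from a noise-only segment
#'   under the same configuration.
#' @param layout optional [sensor_layout()]; checked against the record.
#' @param band detection band in Hz.
#' @param min_consecutive minimum run length (default 3).
#' @param height_k,prominence_k threshold multipliers (default 3).
#' @param spacing_s admissible inter-peak spacing `c(min, max)` in seconds.
#' @return a data.frame of class `footstep_events` with columns `step`,
#'   `side`, `peak_time`, `peak_channel`, `band_energy`.
#' @export
detect_footsteps <- function(record, noise, layout = NULL, band = c(5, 50),
                             min_consecutive = 3, height_k = 3,
                             prominence_k = 3, spacing_s = c(0.25, 2.5)) {
  if (!inherits(noise, "noise_stats"))
    stop("`noise` must come from estimate_noise_stats()", call. = FALSE)
  if (!is.null(layout)) check_layout_record(record, layout)
  if (nrow(record$samples) < record$sample_rate)
    stop("record shorter than the analysis window (1 s)", call. = FALSE)
  ds <- detection_series(record, band)
  pk <- find_peaks(ds$series)
  pk <- pk[pk$height > noise$mean + height_k * noise$sd &
             pk$prominence > prominence_k * noise$sd, , drop = FALSE]
  # enforce minimum spacing, keeping the larger peak
  if (nrow(pk) > 1) {
    keep <- rep(TRUE, nrow(pk))
    ord <- order(pk$height, decreasing = TRUE)
    taken <- numeric(0)
    for (i in ord) {
      t_i <- ds$time[pk$idx[i]]
      if (any(abs(taken - t_i) < spacing_s[1])) keep[i] <- FALSE
      else taken <- c(taken, t_i)
    }
    pk <- pk[keep, , drop = FALSE]
  }
  empty <- structure(
    data.frame(step = integer(), side = character(), peak_time = numeric(),
               peak_channel = character(), band_energy = numeric(),
               stringsAsFactors = FALSE),
    class = c("footstep_events", "data.frame"))
  if (nrow(pk) < min_consecutive) return(empty)

  # group into runs of quasi-regular spacing; footsteps repeat in amplitude
  # as well as spacing, so run-edge peaks far below the run's typical height
  # (stray transients such as the final push-off ring) are trimmed; keep
  # runs >= min_consecutive
  tms <- ds$time[pk$idx]
  gaps <- diff(tms)
  run_id <- cumsum(c(1, gaps < spacing_s[1] - 1e-12 | gaps > spacing_s[2]))
  keep_rows <- integer(0)
  for (rid in unique(run_id)) {
    rows <- which(run_id == rid)
    rel <- function(r) (pk$height[r] - noise$mean) /
      (median(pk$height[rows]) - noise$mean)
    while (length(rows) > 0 && rel(rows[1]) < 0.55) rows <- rows[-1]
    while (length(rows) > 0 && rel(rows[length(rows)]) < 0.55)
      rows <- rows[-length(rows)]
    if (length(rows) >= min_consecutive) keep_rows <- c(keep_rows, rows)
  }
  pk <- pk[keep_rows, , drop = FALSE]
  if (nrow(pk) == 0) return(empty)

  tms <- ds$time[pk$idx]
  chan <- vapply(pk$idx, function(i)
    colnames(ds$per_channel)[which.max(ds$per_channel[i, ])], "")
  structure(
    data.frame(step = seq_len(nrow(pk)),
               side = rep(c("A", "B"), length.out = nrow(pk)),
               peak_time = tms, peak_channel = chan,
               band_energy = pk$height, stringsAsFactors = FALSE),
    class = c("footstep_events", "data.frame"))
}

#' Write detected events as CSV
#' @param events a `footstep_events` data.frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  out <- data.frame(index = events$step, side = events$side,
                    peak_time_s = events$peak_time,
                    peak_channel = events$peak_channel,
                    band_energy = events$band_energy)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
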