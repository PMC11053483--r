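# Floor-adaptive temporal gait parameters: dominant-band extraction,
# foot-strike / foot-off timing, and the six duration parameters.

#' Floor frequency bands
#'
#' The pair of dominant frequency bands a floor imposes on footstep
#' vibrations: a higher band excited by the sharp initial contact (used for
#' foot-strike timing) and a lower band, near the floor's natural
#' frequencies, whose peak marks the start of damped free vibration at foot
#' off. Bands are floor properties: once extracted they can be reused for
#' later traces on the same floor.
#'
#' @param strike_band,off_band numeric `c(f_lo, f_hi)` in Hz; the strike band
#'   centre must exceed the off band centre.
#' @return an object of class `floor_bands`.
#' @export
floor_bands <- function(strike_band, off_band) {
  if (length(strike_band) != 2 || length(off_band) != 2 ||
      strike_band[1] >= strike_band[2] || off_band[1] >= off_band[2])
    stop_field("bands", "each band must be c(f_lo, f_hi) with f_lo < f_hi")
  if (mean(strike_band) <= mean(off_band))
    stop_field("bands", "strike band centre must exceed off band centre")
  structure(list(strike_band = as.numeric(strike_band),
                 off_band = as.numeric(off_band)), class = "floor_bands")
}

#' @export
print.floor_bands <- function(x, ...) {
  cat(sprintf("<floor_bands> strike %.1f-%.1f Hz, off %.1f-%.1f Hz\n",
              x$strike_band[1], x$strike_band[2],
              x$off_band[1], x$off_band[2]))
  invisible(x)
}

# Channel-summed wavelet magnitude spectrum of a record on a common grid.
# The grid starts above the body-weight-transfer content (< 8 Hz) so that
# band extraction sees the floor's ringing response, not the quasi-static
# loading residue.
analysis_spectrum <- function(record, freqs = NULL) {
  fs <- record$sample_rate
  freqs <- freqs %||% seq(8, min(200, 0.45 * fs), by = 2.5)
  tm <- rec_times(record)
  mag <- NULL
  for (ch in rec_sensors(record)) {
    sp <- morlet_cwt(record$samples[, ch], fs, freqs, times = tm)
    mag <- if (is.null(mag)) sp$magnitude else mag + sp$magnitude
  }
  structure(list(freq = freqs, time = tm, magnitude = mag, coef = NULL),
            class = "wavelet_spectrum")
}

#' Group footstep events into gait-cycle pairs
#'
#' A gait cycle runs from one foot's strike to the same foot's next strike and
#' therefore spans two detected footsteps; consecutive footsteps are combined
#' into overlapping pairs (1,2), (2,3), ..., each anchored at its first event.
#'
#' @param events a `footstep_events` data.frame (>= 3 events).
#' @return data.frame with columns `cycle`, `side`, `t_start`, `t_mid`,
#'   `t_end` (`t_end` is `NA` for the last pair, which has no same-foot
#'   return strike).
#' @export
segment_cycles <- function(events) {
  n <- nrow(events)
  if (n < 3) stop("need at least 3 events to segment cycles", call. = FALSE)
  i <- seq_len(n - 1)
  data.frame(cycle = i, side = events$side[i],
             t_start = events$peak_time[i],
             t_mid = events$peak_time[i + 1],
             t_end = c(events$peak_time[i[-length(i)] + 2], NA))
}

# Mean magnitude spectrum over a set of fractional windows of gait cycles.
window_mean_spectrum <- function(spectrum, starts, ends, frac) {
  acc <- numeric(length(spectrum$freq))
  used <- 0L
  for (j in seq_along(starts)) {
    if (is.na(ends[j])) next
    dur <- ends[j] - starts[j]
    t0 <- starts[j] + frac[1] * dur
    t1 <- starts[j] + frac[2] * dur
    cols <- which(spectrum$time >= t0 & spectrum$time <= t1)
    if (length(cols) < 2) next
    acc <- acc + rowMeans(spectrum$magnitude[, cols, drop = FALSE])
    used <- used + 1L
  }
  if (used < 3) stop("need at least 3 usable cycles for band extraction",
                     call. = FALSE)
  acc / used
}

# Contiguous frequency interval above 50% of the spectrum maximum, containing
# the argmax.
dominant_band <- function(freq, value, rel = 0.5) {
  pk <- which.max(value)
  ok <- value >= rel * value[pk]
  lo <- pk
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- pk
  while (hi < length(freq) && ok[hi + 1]) hi <- hi + 1
  c(freq[lo], freq[hi])
}

#' Extract the floor's dominant frequency bands
#'
#' Averages the wavelet magnitude spectrum over the first 0-10% of every gait
#' cycle (where foot strikes occur) and over 60-70% (where foot offs occur);
#' each dominant band is the contiguous frequency interval above 50% of the
#' window average's maximum. Both windows contain the floor's fundamental
#' ring, so the assignment is structural: the foot-off band is extracted
#' first (the damped free vibration near the floor's lowest natural
#' frequency), and the strike band — the higher range, excited by the
#' impulsive contact — is then extracted from the frequencies above the
#' foot-off band's upper edge.
#'
#' @param spectrum a channel-summed `wavelet_spectrum` of the record.
#' @param events a `footstep_events` data.frame (>= 5 events, i.e. 3 full
#'   cycles).
#' @return a [floor_bands()].
#' @export
extract_floor_bands <- function(spectrum, events) {
  n <- nrow(events)
  if (n < 5) stop("need at least 5 events (3 full cycles)", call. = FALSE)
  starts <- events$peak_time[seq_len(n - 2)]
  ends <- events$peak_time[3:n]
  # detected peak times lag the true strikes by the wavelet time smear, so
  # the 0-10% (strike) and 60-70% (foot-off) cycle-phase windows are shifted
  # back accordingly when anchored at the detected peaks
  strike_spec <- window_mean_spectrum(spectrum, starts, ends, c(-0.08, 0.10))
  off_spec <- window_mean_spectrum(spectrum, starts, ends, c(0.52, 0.68))
  off_band <- dominant_band(spectrum$freq, off_spec)
  above <- spectrum$freq > off_band[2]
  if (sum(above) >= 3) {
    strike_band <- dominant_band(spectrum$freq[above], strike_spec[above])
  } else {
    strike_band <- dominant_band(spectrum$freq, strike_spec)
  }
  if (mean(strike_band) > mean(off_band)) floor_bands(strike_band, off_band)
  else floor_bands(off_band, strike_band)
}

#' Foot-strike time from the strike-band series
#'
#' Finds the strike-band peak inside the window, then slides a reverse window
#' (one sample at a time) from the peak towards the valley: the walk stops at
#' the first local minimum or where the series falls below
#' `noise_mean + 3 * noise_sd`, whichever comes first — the time when the
#' vibration starts to rise. When `onset_frac` is set, the onset is then
#' refined to the earliest time the series exceeds that fraction of the local
#' rise (valley-to-peak), which centres the estimate under the wavelet's
#' symmetric time smearing.
#'
#' @param series numeric strike-band band-sum series.
#' @param time matching time axis (seconds).
#' @param window `c(t0, t1)` search window.
#' @param threshold noise threshold (absolute units).
#' @param onset_frac optional fraction in (0, 1) for the rise-refinement rule.
#' @return the strike time in seconds, or `NA` if no peak exceeds the
#'   threshold inside the window.
#' @export
detect_strike_time <- function(series, time, window, threshold,
                               onset_frac = 0.5) {
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 3) return(NA_real_)
  seg <- series[idx]
  pk_local <- which.max(seg)
  if (seg[pk_local] <= threshold) return(NA_real_)
  j <- pk_local
  while (j > 1 && seg[j - 1] < seg[j] && seg[j - 1] > threshold) j <- j - 1
  valley <- j
  if (is.null(onset_frac)) return(time[idx[valley]])
  level <- seg[valley] + onset_frac * (seg[pk_local] - seg[valley])
  ks <- valley + which(seg[valley:pk_local] >= level)[1] - 1L
  if (is.na(ks)) ks <- valley
  time[idx[ks]]
}

#' Foot-off time from the off-band series
#'
#' The foot off is the peak of the lower-frequency (natural-frequency)
#' component: damped free vibration starts there. Returns the earliest argmax
#' of the off-band series inside the window, or `NA` (event flagged missing)
#' when the series never exceeds the threshold — such cycles are dropped from
#' parameter averaging rather than imputed.
#'
#' @param series numeric off-band band-sum series.
#' @param time matching time axis.
#' @param window `c(t0, t1)` search window.
#' @param threshold noise threshold (absolute units).
#' @return the foot-off time in seconds, or `NA`.
#' @export
detect_off_time <- function(series, time, window, threshold) {
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 2) return(NA_real_)
  seg <- series[idx]
  pk <- which.max(seg)        # which.max returns the earliest maximum (ties)
  if (seg[pk] <= threshold) return(NA_real_)
  time[idx[pk]]
}

#' Temporal gait parameters from strike and off times
#'
#' Given per-cycle foot-strike times `t_i^s` and foot-off times `t_i^o`
#' (cycle i is anchored at footstep i; `t_{i+1}^s` is the opposite foot's
#' strike):
#' \itemize{
#'   \item step time `= t_{i+1}^s - t_i^s`
#'   \item stride time `= t_{i+2}^s - t_i^s`
#'   \item stance time `= t_i^o - t_i^s`
#'   \item swing time `= t_{i+2}^s - t_i^o`
#'   \item single-support time `= t_{i+1}^s - t_{i-1}^o`
#'   \item double-support 1 `= t_{i-1}^o - t_i^s`
#'   \item double-support 2 `= t_i^o - t_{i+1}^s`
#' }
#' Parameters undefined at the trace boundary are `NA` (omitted, not
#' zero-filled). The algebraic identities (step + next step = stride,
#' stance + swing = stride, single-support_i = swing_{i-1}) hold exactly.
#'
#' @param cycles data.frame with columns `t_strike` (strictly increasing),
#'   `t_off` (may contain `NA`), and optionally `side`.
#' @return data.frame with one row per cycle: `cycle`, `side`, `t_strike`,
#'   `t_off`, `step_time`, `stride_time`, `stance_time`, `swing_time`,
#'   `single_support`, `double_support1`, `double_support2`.
#' @export
compute_temporal_params <- function(cycles) {
  ts <- cycles$t_strike
  to <- cycles$t_off
  n <- length(ts)
  if (n < 2) stop("need at least 2 cycles", call. = FALSE)
  if (any(diff(ts) <= 0))
    stop("strike times must be strictly increasing", call. = FALSE)
  if (any(!is.na(to) & to <= ts))
    stop("each foot-off must follow its foot-strike", call. = FALSE)
  lead <- function(v, k) c(v[-seq_len(k)], rep(NA_real_, k))
  lag1 <- function(v) c(NA_real_, v[-n])
  step_time <- lead(ts, 1) - ts
  stride_time <- lead(ts, 2) - ts
  stance_time <- to - ts
  swing_time <- lead(ts, 2) - to
  single_support <- lead(ts, 1) - lag1(to)
  double_support1 <- lag1(to) - ts
  double_support2 <- to - lead(ts, 1)
  data.frame(
    cycle = seq_len(n),
    side = cycles$side %||% rep(c("A", "B"), length.out = n),
    t_strike = ts, t_off = to,
    step_time = step_time, stride_time = stride_time,
    stance_time = stance_time, swing_time = swing_time,
    single_support = single_support,
    double_support1 = double_support1, double_support2 = double_support2,
    stringsAsFactors = FALSE
  )
}

#' Floor-adaptive temporal parameter estimation
#'
#' Full temporal pipeline for one trace: channel-summed wavelet spectrum,
#' dominant-band extraction (or reuse of cached `bands` from the same floor),
#' strike/off timing per cycle, and the six duration parameters.
#'
#' @param record a [vibration_record()] (temporal-path bandwidth, i.e.
#'   already lowpassed/decimated to ~1 kHz).
#' @param events a `footstep_events` data.frame from [detect_footsteps()].
#' @param bands optional [floor_bands()] cached from a previous trace on the
#'   same floor; extracted from this trace when `NULL`.
#' @param quiet_interval `c(t0, t1)` noise-only interval; defaults to the
#'   stretch before the first detected footstep.
#' @param stance_fraction_hint prior stance fraction of the stride used to
#'   centre the foot-off search window (the window spans that fraction
#'   -0.08/+0.25 of the cycle).
#' @param onset_frac passed to [detect_strike_time()].
#' @param freqs optional CWT frequency grid.
#' @return list with `bands`, `cycles` (strike/off table), `params`
#'   ([compute_temporal_params()] output) and `spectrum`.
#' @export
estimate_temporal <- function(record, events, bands = NULL,
                              quiet_interval = NULL,
                              stance_fraction_hint = 0.64,
                              onset_frac = 0.5, freqs = NULL) {
  n <- nrow(events)
  if (n < 3) stop("need at least 3 detected footsteps", call. = FALSE)
  spectrum <- analysis_spectrum(record, freqs)
  if (is.null(bands)) bands <- extract_floor_bands(spectrum, events)

  quiet_interval <- quiet_interval %||%
    c(spectrum$time[1], events$peak_time[1] - 0.3)
  strike_series <- band_sum(spectrum, bands$strike_band[1],
                            bands$strike_band[2])
  off_series <- band_sum(spectrum, bands$off_band[1], bands$off_band[2])
  thr <- function(series) {
    cols <- which(spectrum$time >= quiet_interval[1] &
                    spectrum$time <= quiet_interval[2])
    if (length(cols) >= 0.2 * record$sample_rate) {
      q <- series[cols]
      mean(q) + 3 * sd(q)
    } else {
      # fallback: series values below the median approximate the noise floor
      q <- series[series <= median(series)]
      mean(q) + 3 * sd(q)
    }
  }
  thr_strike <- thr(strike_series)
  thr_off <- thr(off_series)

  pt <- events$peak_time
  gap <- diff(pt)
  med_gap <- median(gap)
  gap_prev <- c(med_gap, gap)
  gap_next <- c(gap, med_gap)
  t_s <- vapply(seq_len(n), function(i) {
    win <- c(pt[i] - 0.45 * gap_prev[i], pt[i] + 0.25 * gap_next[i])
    detect_strike_time(strike_series, spectrum$time, win, thr_strike,
                       onset_frac = onset_frac)
  }, 0)

  t_o <- rep(NA_real_, n)
  med_step <- median(diff(t_s), na.rm = TRUE)
  for (i in seq_len(n)) {
    if (is.na(t_s[i])) next
    stride_i <- if (i + 2 <= n && !is.na(t_s[i + 2])) t_s[i + 2] - t_s[i]
                else 2 * med_step
    # foot off falls at 60-70% of the gait cycle; the upper edge carries a
    # small allowance for the wavelet time smear of the off-band ring
    win <- t_s[i] + c(0.62, 0.72) * stride_i
    win[2] <- min(win[2], spectrum$time[length(spectrum$time)])
    t_o[i] <- detect_off_time(off_series, spectrum$time, win, thr_off)
  }

  ok <- !is.na(t_s)
  cycles <- data.frame(t_strike = t_s[ok], t_off = t_o[ok],
                       side = events$side[ok], stringsAsFactors = FALSE)
  params <- if (sum(ok) >= 2) compute_temporal_params(cycles) else NULL
  list(bands = bands, cycles = cycles, params = params, spectrum = spectrum)
}
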