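# Noise filtering: zero-phase lowpass for electrical noise, frequency-domain
# Wiener gain for stationary environmental noise.

#' Zero-phase Butterworth lowpass
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so the
#' filter has no group delay and event times are not shifted. The default
#' cutoffs used by the pipeline are 500 Hz for the temporal/indicator path and
#' 2500 Hz for the spatial (arrival-picking) path.
#'
#' @param record a [vibration_record()].
#' @param cutoff_hz cutoff frequency, 0 < cutoff < Nyquist.
#' @return the filtered [vibration_record()].
#' @export
lowpass <- function(record, cutoff_hz) {
  fs <- record$sample_rate
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop_field("cutoff_hz", sprintf("must be in (0, %g) for this record",
                                    fs / 2))
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  n <- nrow(record$samples)
  # odd-reflection padding suppresses filtfilt's zero-state edge transients
  p <- min(n - 1L, ceiling(10 * fs / cutoff_hz))
  out <- record
  out$samples <- apply(record$samples, 2, function(ch) {
    padded <- c(2 * ch[1] - rev(ch[2:(p + 1)]), ch,
                2 * ch[n] - rev(ch[(n - p):(n - 1)]))
    signal::filtfilt(bf, padded)[(p + 1):(p + n)]
  })
  colnames(out$samples) <- colnames(record$samples)
  out
}

#' Wiener denoising from a noise-only segment
#'
#' Per channel, the noise power spectral density is estimated from
#' `noise_segment` by Welch averaging and a frequency-domain Wiener gain
#' `max(1 - Pn(f) / Px(f), gain_floor)` is applied to the record's spectrum.
#' Stationary noise power is reduced while impulsive components (whose
#' spectral power exceeds the noise floor) are retained. The gain floor
#' avoids musical-noise artefacts.
#'
#' @param record a [vibration_record()].
#' @param noise_segment a [vibration_record()] containing only environmental
#'   noise; sensor ids must be a superset of the record's; at least 1 s long
#'   (3 s recommended).
#' @param gain_floor minimum spectral gain (default 0.05).
#' @return the denoised [vibration_record()].
#' @export
wiener_denoise <- function(record, noise_segment, gain_floor = 0.05) {
  fs <- record$sample_rate
  if (abs(noise_segment$sample_rate - fs) > 1e-9)
    stop("record and noise segment sample rates differ", call. = FALSE)
  if (nrow(noise_segment$samples) > nrow(record$samples))
    stop("noise segment is longer than the record", call. = FALSE)
  if (nrow(noise_segment$samples) < fs)
    stop("noise segment must be at least 1 s long", call. = FALSE)
  missing <- setdiff(rec_sensors(record), rec_sensors(noise_segment))
  if (length(missing))
    stop(sprintf("noise segment is missing channels: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  n <- nrow(record$samples)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs_folded <- pmin(freqs, fs - freqs)
  out <- record
  for (ch in rec_sensors(record)) {
    x <- record$samples[, ch]
    pw <- welch_psd(noise_segment$samples[, ch], fs)
    pn <- approx(pw$freq, pw$psd, xout = freqs_folded, rule = 2)$y
    X <- fft(x)
    px <- Mod(X)^2 / (n * fs)
    gain <- pmax(1 - pn / pmax(px, .Machine$double.xmin), gain_floor)
    out$samples[, ch] <- Re(fft(X * gain, inverse = TRUE)) / n
  }
  out
}

#' Decimate a record by an integer factor
#'
#' Anti-alias lowpass (0.45x the target rate) followed by sample picking.
#' The pipeline uses this to run the temporal path at about 1 kHz when
#' records are sampled faster for the spatial path.
#'
#' @param record a [vibration_record()].
#' @param factor integer decimation factor; returned unchanged for 1.
#' @return the decimated [vibration_record()].
#' @export
decimate_record <- function(record, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(record)
  fs_new <- record$sample_rate / factor
  filtered <- lowpass(record, 0.45 * fs_new)
  idx <- seq(1L, nrow(filtered$samples), by = factor)
  vibration_record(filtered$samples[idx, , drop = FALSE], fs_new,
                   start_time = record$start_time)
}
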