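# Forward simulator: scripted walks over a reduced modal floor model.
#
# The floor is represented by a handful of damped modes; the response at a
# sensor is the footstep force convolved with the modal impulse response
#   h(t) = sum_j w_j * exp(-xi_j * omega_j * t) * sin(omega_dj * t),
# delayed by distance / v(x_footstep) and attenuated by exp(-alpha * distance).
# Wave propagation is pure delay + exponential amplitude decay (no dispersion),
# and the velocity is taken from the 1-D profile at the footstep's x.

#' Floor vibration mode
#'
#' One damped mode of the reduced floor model. The `weight` collapses the mode
#' shape products at the sensing and excitation locations into a single scalar.
#'
#' @param frequency_hz natural frequency in Hz (> 0).
#' @param damping_ratio dimensionless damping ratio, in (0, 1).
#' @param weight dimensionless modal shape factor.
#' @return an object of class `floor_mode`.
#' @export
floor_mode <- function(frequency_hz, damping_ratio, weight = 1) {
  if (!is.numeric(frequency_hz) || frequency_hz <= 0)
    stop_field("frequency_hz", "must be > 0")
  if (damping_ratio <= 0 || damping_ratio >= 1)
    stop_field("damping_ratio", "must be in (0, 1)")
  if (!is.finite(weight)) stop_field("weight", "must be finite")
  structure(list(frequency_hz = frequency_hz, damping_ratio = damping_ratio,
                 weight = weight), class = "floor_mode")
}

#' Floor model
#'
#' A reduced modal floor: a list of [floor_mode()]s, a wave-velocity profile,
#' an exponential amplitude-attenuation rate and a rectangular extent.
#'
#' @param modes list of [floor_mode()] (at least one).
#' @param velocity either a single wave speed in m/s (constant over the floor)
#'   or a [velocity_profile()].
#' @param attenuation_rate amplitude decay rate in 1/m (>= 0).
#' @param extent numeric `c(x_min, x_max, y_min, y_max)` in metres.
#' @return an object of class `floor_model`.
#' @export
floor_model <- function(modes, velocity = 120, attenuation_rate = 0.5,
                        extent = c(-1, 12, -2, 2)) {
  if (inherits(modes, "floor_mode")) modes <- list(modes)
  if (length(modes) < 1 || !all(vapply(modes, inherits, TRUE, "floor_mode")))
    stop_field("modes", "must be a non-empty list of floor_mode objects")
  if (attenuation_rate < 0) stop_field("attenuation_rate", "must be >= 0")
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop_field("extent", "must be c(x_min, x_max, y_min, y_max)")
  if (is.numeric(velocity) && length(velocity) == 1) {
    if (velocity <= 0) stop_field("velocity", "must be positive")
    velocity <- velocity_profile(c(velocity, 0, 0, 0, 0),
                                 valid_range = extent[1:2])
  }
  if (!inherits(velocity, "velocity_profile"))
    stop_field("velocity", "must be a number or a velocity_profile")
  structure(list(modes = modes, velocity = velocity,
                 attenuation_rate = attenuation_rate, extent = extent),
            class = "floor_model")
}

#' Floor presets
#'
#' Illustrative modal parameters for the two floor constructions the pipeline
#' is most often used on. Each preset has a low structural mode in the
#' natural-frequency band the detector watches (5-50 Hz) and a high
#' plate/local mode that carries the response of a sharp initial contact. Values are
#' presets chosen to reproduce the qualitative behaviour of such floors
#' (wood: lower modal frequencies, slower waves; concrete: higher frequencies,
#' faster waves, stronger attenuation) — they are not measurements of any
#' particular building.
#'
#' @param type `"wood"` or `"concrete"`.
#' @param velocity override the wave velocity (m/s or [velocity_profile()]);
#'   defaults to 90 m/s (wood) or 180 m/s (concrete).
#' @return a [floor_model()].
#' @export
floor_preset <- function(type = c("wood", "concrete"), velocity = NULL) {
  type <- match.arg(type)
  # weights grow with modal frequency: geophones sense velocity, which
  # scales each mode's contribution by its angular frequency
  if (type == "wood") {
    modes <- list(
      floor_mode(12, 0.22, 1.0), floor_mode(60, 0.09, 12.0)
    )
    floor_model(modes, velocity %||% 90, attenuation_rate = 0.4)
  } else {
    modes <- list(
      floor_mode(20, 0.18, 1.0), floor_mode(130, 0.08, 12.0)
    )
    floor_model(modes, velocity %||% 180, attenuation_rate = 0.7)
  }
}

#' Walk plan
#'
#' The scripted gait statistics a synthetic walk is drawn from. Step lengths,
#' widths and times are independent normals; side A step lengths are scaled by
#' `left_right_length_ratio` to emulate asymmetric gait. Defaults follow
#' population means for healthy adult walking (step length 0.678 m, step time
#' 0.581 s, stance 64.3% of the stride, giving the 0.166 s double-support time of the same reference gait); `mean_step_width` is the lateral
#' separation between the left- and right-foot lines, roughly twice the
#' step-width gait parameter.
#'
#' @param n_steps number of footsteps (>= 3; detection needs three impulses).
#' @param mean_step_length,step_length_sd metres.
#' @param mean_step_width,step_width_sd metres.
#' @param mean_step_time,step_time_sd seconds.
#' @param stance_fraction fraction of the stride during which the foot is on
#'   the floor, in (0, 1).
#' @param left_right_length_ratio side-A/side-B step length ratio (1 =
#'   symmetric).
#' @param contact_type `"heel"`, `"midfoot"` or `"toe"` (applied to all
#'   steps, or a length-2 vector giving side A and side B types).
#' @param start_time time of the first strike in seconds; the default leaves
#'   a 3 s noise-only lead-in for noise-statistics estimation.
#' @param seed integer RNG seed.
#' @return an object of class `walk_plan`.
#' @export
walk_plan <- function(n_steps = 10,
                      mean_step_length = 0.678, step_length_sd = 0.02,
                      mean_step_width = 0.17, step_width_sd = 0.015,
                      mean_step_time = 0.581, step_time_sd = 0.02,
                      stance_fraction = 0.643,
                      left_right_length_ratio = 1,
                      contact_type = "heel",
                      start_time = 3,
                      seed = 1) {
  if (n_steps < 3) stop_field("n_steps", "must be >= 3")
  for (f in c("mean_step_length", "mean_step_width", "mean_step_time")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0) stop_field(f, "must be > 0")
  }
  for (f in c("step_length_sd", "step_width_sd", "step_time_sd")) {
    if (get(f) < 0) stop_field(f, "must be >= 0")
  }
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop_field("stance_fraction", "must be in (0, 1)")
  if (left_right_length_ratio <= 0)
    stop_field("left_right_length_ratio", "must be > 0")
  if (!all(contact_type %in% c("heel", "midfoot", "toe")))
    stop_field("contact_type", "must be heel, midfoot or toe")
  structure(list(
    n_steps = as.integer(n_steps),
    mean_step_length = mean_step_length, step_length_sd = step_length_sd,
    mean_step_width = mean_step_width, step_width_sd = step_width_sd,
    mean_step_time = mean_step_time, step_time_sd = step_time_sd,
    stance_fraction = stance_fraction,
    left_right_length_ratio = left_right_length_ratio,
    contact_type = contact_type, start_time = start_time,
    seed = as.integer(seed)
  ), class = "walk_plan")
}

#' Generate a scripted walk
#'
#' Draws per-step lengths, widths and times from the plan and returns the
#' ground truth for every footstep: strike time, off time, location, side and
#' contact type. Sides alternate A, B, A, ...; x advances by the per-step
#' lengths from 0; y alternates +/- `mean_step_width / 2` plus noise; foot-off
#' times are `t_strike + stance_fraction * local stride time` (the stride to
#' the same foot's next strike, extrapolated from the mean step time for the
#' last two footsteps). Deterministic for a fixed seed.
#'
#' @param plan a [walk_plan()].
#' @return a data.frame of class `gait_truth` with columns `step`, `side`,
#'   `t_strike`, `t_off`, `x`, `y`, `contact_type`.
#' @examples
#' truth <- generate_walk(walk_plan(n_steps = 5, step_length_sd = 0,
#'                                  step_width_sd = 0, step_time_sd = 0))
#' truth$x
#' @export
generate_walk <- function(plan) {
  stopifnot(inherits(plan, "walk_plan"))
  set.seed(plan$seed)
  n <- plan$n_steps
  side <- rep(c("A", "B"), length.out = n)
  r <- plan$left_right_length_ratio
  # step length i = advance from footstep i-1 to i, owned by footstep i's side
  len_mean <- ifelse(side == "A", plan$mean_step_length * r,
                     plan$mean_step_length)
  lens <- pmax(rnorm(n, len_mean, plan$step_length_sd), 0.05)
  x <- cumsum(c(0, lens[-1]))
  y <- ifelse(side == "A", 1, -1) * plan$mean_step_width / 2 +
    rnorm(n, 0, plan$step_width_sd)
  dts <- pmax(rnorm(n, plan$mean_step_time, plan$step_time_sd), 0.15)
  t_strike <- plan$start_time + cumsum(c(0, dts[-1]))
  stride <- c(t_strike[-(1:2)] - t_strike[seq_len(n - 2)],
              rep(2 * plan$mean_step_time, 2))
  t_off <- t_strike + plan$stance_fraction * stride
  contact <- rep(plan$contact_type, length.out = 2)[match(side, c("A", "B"))]
  structure(
    data.frame(step = seq_len(n), side = side, t_strike = t_strike,
               t_off = t_off, x = x, y = y, contact_type = contact,
               stringsAsFactors = FALSE),
    class = c("gait_truth", "data.frame")
  )
}

#' Write / read footstep ground truth as CSV
#'
#' Columns: `step_index, side, t_strike_s, t_off_s, x_m, y_m, contact_type`.
#'
#' @param truth a `gait_truth` data.frame from [generate_walk()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- data.frame(step_index = truth$step, side = truth$side,
                    t_strike_s = truth$t_strike, t_off_s = truth$t_off,
                    x_m = truth$x, y_m = truth$y,
                    contact_type = truth$contact_type)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(
    data.frame(step = df$step_index, side = df$side, t_strike = df$t_strike_s,
               t_off = df$t_off_s, x = df$x_m, y = df$y_m,
               contact_type = df$contact_type, stringsAsFactors = FALSE),
    class = c("gait_truth", "data.frame")
  )
}

#' Footstep force profile
#'
#' Builds a non-negative force time series for one stance from raised-cosine
#' building blocks. The three initial-contact types differ in their spectra:
#' \describe{
#'   \item{heel}{a short impulse at initial contact (high-frequency energy)
#'     followed by a body-weight hump that ends in a fairly rapid push-off
#'     release at the end of stance (low-frequency energy and a burst of
#'     natural-frequency floor ringing at foot off).}
#'   \item{midfoot}{a single broad smooth pulse spanning the stance — lower
#'     bandwidth than heel, no sharp contact transient.}
#'   \item{toe}{the short impulse only, with no roll/body-weight component —
#'     predominantly high-frequency energy.}
#' }
#'
#' @param contact_type `"heel"`, `"midfoot"` or `"toe"`.
#' @param stance_duration stance duration in seconds (> 0).
#' @param peak_amplitude amplitude of the contact transient (arbitrary force
#'   units; the body-weight hump scales with it).
#' @param sample_rate Hz.
#' @param onset_time onset of the stance in seconds (metadata only; `samples`
#'   always start at the onset).
#' @return an object of class `footstep_force`: list with `samples` (force
#'   series over `[0, stance_duration]`), `sample_rate`, `contact_type`,
#'   `onset_time`, `stance_duration`, `peak_amplitude`.
#' @export
make_footstep_force <- function(contact_type = c("heel", "midfoot", "toe"),
                                stance_duration, peak_amplitude = 1,
                                sample_rate = 1000, onset_time = 0) {
  contact_type <- match.arg(contact_type)
  if (stance_duration <= 0) stop_field("stance_duration", "must be > 0")
  n <- max(2L, round(stance_duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  T <- stance_duration
  A <- peak_amplitude

  # raised cosine centred at c with half-width hw
  rc <- function(t, c, hw) {
    ifelse(abs(t - c) <= hw, 0.5 * (1 + cos(pi * (t - c) / hw)), 0)
  }
  # cosine smoothstep from 0 at a to 1 at b
  s_up <- function(t, a, b) {
    u <- pmin(pmax((t - a) / (b - a), 0), 1)
    0.5 - 0.5 * cos(pi * u)
  }

  # end-weighted unloading: zero slope at release onset and the steepest
  # change right at foot-off, so the natural-frequency ring it excites
  # peaks at the foot-off instant (free vibration starts there)
  s_dn_end <- function(t, a, b, p = 4) {
    u <- pmin(pmax((t - a) / (b - a), 0), 1)
    1 - u^p
  }
  imp_hw <- min(0.003, T / 6)               # ~6 ms contact transient
  impulse <- A * rc(t, imp_hw, imp_hw)
  f <- switch(contact_type,
    heel = {
      drop <- min(0.08, 0.3 * T)            # push-off release duration
      hump <- 0.45 * A * s_up(t, 0.05 * T, 0.35 * T) *
        s_dn_end(t, T - drop, T)
      impulse + hump
    },
    midfoot = {
      0.7 * A * s_up(t, 0, 0.35 * T) * s_dn_end(t, T - 0.25 * T, T, p = 2)
    },
    toe = impulse
  )
  f[f < 0] <- 0
  structure(list(samples = f, sample_rate = sample_rate,
                 contact_type = contact_type, onset_time = onset_time,
                 stance_duration = stance_duration,
                 peak_amplitude = peak_amplitude),
            class = "footstep_force")
}

# Modal impulse response of a floor model, sampled at fs, truncated where the
# slowest-decaying mode has fallen to 1e-4 of its initial amplitude.
# The displacement response of mode j is w_j e^{-xi w t} sin(w_d t); geophones
# sense floor VELOCITY, so the kernel is its time derivative (normalized per
# mode by w_d so modal weights keep their displacement-scale meaning):
# e^{-xi w t} (cos(w_d t) - (xi w / w_d) sin(w_d t)). This kills quasi-static
# (near-DC) content: a slowly varying body-weight force produces almost no
# sensed signal, while sharp transients ring the modes.
modal_impulse_response <- function(model, fs) {
  gammas <- vapply(model$modes, function(m)
    m$damping_ratio * 2 * pi * m$frequency_hz, 0)
  t_max <- min(2.5, log(1e4) / min(gammas))
  t <- seq(0, t_max, by = 1 / fs)
  h <- numeric(length(t))
  for (m in model$modes) {
    om <- 2 * pi * m$frequency_hz
    om_d <- om * sqrt(1 - m$damping_ratio^2)
    g <- m$damping_ratio * om
    h <- h + m$weight * exp(-g * t) * (cos(om_d * t) - (g / om_d) * sin(om_d * t))
  }
  h
}

# FFT linear convolution, full ("open") length.
fft_conv <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nfft <- nextn(n, 2)
  re <- Re(fft(fft(c(a, numeric(nfft - length(a)))) *
                 fft(c(b, numeric(nfft - length(b)))), inverse = TRUE)) / nfft
  re[seq_len(n)]
}

#' Simulate a multichannel vibration record
#'
#' For every footstep in `truth`, the contact-type force profile is convolved
#' with the floor's modal impulse response; each sensor receives that response
#' delayed by `distance / v(x_footstep)` and scaled by
#' `exp(-attenuation_rate * distance)`, plus white Gaussian noise.
#'
#' @param model a [floor_model()].
#' @param truth a `gait_truth` data.frame ([generate_walk()]); may have zero
#'   rows for a noise-only record.
#' @param layout a [sensor_layout()].
#' @param sample_rate Hz; must be at least 4x the highest modal frequency.
#' @param noise_sd standard deviation of the additive noise (signal units).
#' @param seed integer seed for the noise (ignored when `noise_sd = 0`).
#' @param duration record length in seconds; default covers the last foot-off
#'   plus a 1.5 s tail.
#' @param amplitude per-footstep force amplitude (recycled).
#' @return a [vibration_record()].
#' @export
simulate_record <- function(model, truth, layout, sample_rate = 1000,
                            noise_sd = 0, seed = NULL, duration = NULL,
                            amplitude = 1) {
  stopifnot(inherits(model, "floor_model"), inherits(layout, "sensor_layout"))
  fs <- sample_rate
  if (fs <= 0) stop_field("sample_rate", "must be positive")
  fmax <- max(vapply(model$modes, `[[`, 0, "frequency_hz"))
  if (fs < 4 * fmax)
    stop_field("sample_rate", sprintf(
      "must be >= 4x the highest modal frequency (%g Hz)", 4 * fmax))
  n_steps <- nrow(truth)
  if (n_steps > 0) {
    out_x <- truth$x < model$extent[1] | truth$x > model$extent[2] |
      truth$y < model$extent[3] | truth$y > model$extent[4]
    if (any(out_x))
      stop(sprintf("footstep(s) %s outside the floor extent",
                   paste(truth$step[out_x], collapse = ", ")), call. = FALSE)
  }
  duration <- duration %||%
    (if (n_steps > 0) max(truth$t_off) + 1.5 else 2)
  n <- ceiling(duration * fs)
  k <- nrow(layout)
  sig <- matrix(0, n, k, dimnames = list(NULL, layout$sensor))

  if (n_steps > 0) {
    h <- modal_impulse_response(model, fs)
    amplitude <- rep(amplitude, length.out = n_steps)
    for (i in seq_len(n_steps)) {
      force <- make_footstep_force(truth$contact_type[i],
                                   truth$t_off[i] - truth$t_strike[i],
                                   peak_amplitude = amplitude[i],
                                   sample_rate = fs)
      resp <- fft_conv(force$samples, h)
      v <- predict(model$velocity, truth$x[i])
      d <- layout_distances(layout, truth$x[i], truth$y[i])
      for (j in seq_len(k)) {
        delay_n <- round((truth$t_strike[i] + d[j] / v) * fs)
        idx <- delay_n + seq_along(resp)
        keep <- idx >= 1 & idx <= n
        sig[idx[keep], j] <- sig[idx[keep], j] +
          exp(-model$attenuation_rate * d[j]) * resp[keep]
      }
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + matrix(rnorm(n * k, 0, noise_sd), n, k)
  }
  vibration_record(sig, fs)
}

#' Default four-sensor walkway layout
#'
#' Four sensors staggered on both sides of a straight walkway, spaced 2 m
#' longitudinally and 1 m from the path, mirroring a typical deployment.
#'
#' @return a [sensor_layout()].
#' @export
default_layout <- function() {
  sensor_layout(c("S1", "S2", "S3", "S4"),
                x = c(0, 2, 4, 6), y = c(-1, 1, -1, 1))
}

#' Simulate a complete walk
#'
#' Convenience wrapper: generates the ground truth from the plan and the
#' record from the floor model, with noise expressed either directly
#' (`noise_sd`) or as a signal-to-noise ratio in dB (`snr_db`, the ratio of
#' the clean record's mean power over the active walking span — first strike
#' to last foot-off, strongest channel — to the noise power).
#'
#' @param plan a [walk_plan()].
#' @param floor a [floor_model()] (default: concrete preset).
#' @param layout a [sensor_layout()].
#' @param sample_rate Hz.
#' @param snr_db SNR in dB; ignored when `noise_sd` is given.
#' @param noise_sd explicit noise standard deviation.
#' @param noise_seed seed for the noise draw (defaults to `plan$seed + 1e6`).
#' @return list with `record`, `truth`, `plan`, `floor`, `layout`, `noise_sd`.
#' @export
simulate_walk <- function(plan, floor = floor_preset("concrete"),
                          layout = default_layout(), sample_rate = 1000,
                          snr_db = Inf, noise_sd = NULL, noise_seed = NULL) {
  truth <- generate_walk(plan)
  clean <- simulate_record(floor, truth, layout, sample_rate)
  if (is.null(noise_sd)) {
    if (is.finite(snr_db)) {
      tm <- rec_times(clean)
      act <- tm >= min(truth$t_strike) & tm <= max(truth$t_off)
      pow <- max(colMeans(clean$samples[act, , drop = FALSE]^2))
      noise_sd <- sqrt(pow) / 10^(snr_db / 20)
    } else noise_sd <- 0
  }
  rec <- clean
  if (noise_sd > 0) {
    set.seed(noise_seed %||% (plan$seed + 1000000L))
    rec$samples <- clean$samples +
      matrix(rnorm(length(clean$samples), 0, noise_sd),
             nrow(clean$samples), ncol(clean$samples))
  }
  list(record = rec, truth = truth, plan = plan, floor = floor,
       layout = layout, noise_sd = noise_sd)
}
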