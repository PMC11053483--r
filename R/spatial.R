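# Floor-adaptive spatial gait parameters: velocity-profile calibration,
# wave-arrival picking, TDoA grid-search localization, trajectory regression,
# and step length/width/angle/stride.

#' Wave-velocity profile
#'
#' Position-dependent wave propagation speed along the walkway, modelled as a
#' quartic polynomial `v(x) = b0 + b1 x + b2 x^2 + b3 x^3 + b4 x^4`.
#' Evaluation clamps `x` to `valid_range` (nearest-boundary extrapolation)
#' and the velocity to `clamp` (default 30-300 m/s, the physically plausible
#' range for common floors).
#'
#' @param coefficients numeric `c(b0, b1, b2, b3, b4)`.
#' @param valid_range `c(x_min, x_max)` in metres.
#' @param clamp `c(v_min, v_max)` in m/s.
#' @return an object of class `velocity_profile`.
#' @export
velocity_profile <- function(coefficients, valid_range = c(0, 10),
                             clamp = c(30, 300)) {
  coefficients <- rep(as.numeric(coefficients), length.out = 5)
  if (!all(is.finite(coefficients)))
    stop_field("coefficients", "must be finite")
  structure(list(coefficients = coefficients, valid_range = valid_range,
                 clamp = clamp), class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf(
    "<velocity_profile> v(x) = %s over [%g, %g] m, clamped to [%g, %g] m/s\n",
    paste(sprintf("%.4g x^%d", x$coefficients, 0:4), collapse = " + "),
    x$valid_range[1], x$valid_range[2], x$clamp[1], x$clamp[2]))
  invisible(x)
}

#' Evaluate a velocity profile
#' @param object a [velocity_profile()].
#' @param x positions in metres.
#' @param ... unused.
#' @return velocities in m/s, clamped as documented.
#' @export
predict.velocity_profile <- function(object, x, ...) {
  xc <- pmin(pmax(x, object$valid_range[1]), object$valid_range[2])
  v <- drop(outer(xc, 0:4, `^`) %*% object$coefficients)
  pmin(pmax(v, object$clamp[1]), object$clamp[2])
}

#' Fit a quartic velocity profile
#'
#' Least-squares fit of `v(x)` to measured (position, velocity) samples,
#' following the two-span cross-section rationale for a 4th-order model.
#'
#' @param x footstep positions in metres (>= 6, spanning the walkway).
#' @param v measured velocities in m/s.
#' @param clamp velocity clamp passed to the profile.
#' @return a [velocity_profile()] with `valid_range` set to the sample range.
#' @export
fit_velocity_profile <- function(x, v, clamp = c(30, 300)) {
  if (length(x) < 6) stop("need at least 6 velocity samples", call. = FALSE)
  if (length(unique(round(x, 6))) < 5 || diff(range(x)) < 1e-6)
    stop("degenerate x spread: need at least 5 distinct positions",
         call. = FALSE)
  fit <- lm(v ~ poly(x, 4, raw = TRUE))
  velocity_profile(coef(fit), valid_range = range(x), clamp = clamp)
}

#' Wave-arrival time on one channel
#'
#' Picks the wave arrival as the first time the channel's analytic-signal
#' envelope exceeds the noise threshold, searching from the foot-strike time
#' up to the envelope peak (the footstep force grows after initial contact,
#' so the arrival lies between the strike and the peak).
#'
#' @param env channel envelope (from [envelope()] of the spatial-bandwidth
#'   channel).
#' @param time matching time axis.
#' @param t_strike foot-strike time (search start).
#' @param t_peak end of the search window; default the envelope argmax within
#'   150 ms of the strike.
#' @param threshold noise threshold (absolute envelope units).
#' @param not_before optional lower bound (used when re-searching a pick that
#'   violated the distance ordering).
#' @param sustain_s duration the series must stay above the threshold for a
#'   crossing to count as a wave arrival (default 3 ms); brief noise
#'   excursions above the threshold are rejected by this rule.
#' @return arrival time in seconds, or `NA` when the threshold is never
#'   crossed (sensor excluded from this footstep).
#' @export
estimate_arrival_time <- function(env, time, t_strike, t_peak = NULL,
                                  threshold, not_before = NULL,
                                  sustain_s = 0.003) {
  if (is.null(t_peak)) {
    idx0 <- which(time > t_strike & time <= t_strike + 0.15)
    if (length(idx0) == 0) return(NA_real_)
    t_peak <- time[idx0[which.max(env[idx0])]]
  }
  lo <- max(t_strike, not_before %||% -Inf)
  idx <- which(time > lo & time <= t_peak)
  if (length(idx) == 0) return(NA_real_)
  dt <- median(diff(time))
  p <- max(1L, round(sustain_s / dt))
  above <- env[idx[1]:min(idx[length(idx)] + p, length(env))] > threshold
  run <- rle(above)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= p)[1]
  if (is.na(hit)) return(NA_real_)
  start <- if (hit == 1) 1L else ends[hit - 1] + 1L
  if (start > length(idx)) return(NA_real_)
  time[idx[start]]
}

# Arrivals for one footstep across sensors, with the distance-ordering check:
# walking sensors in increasing expected distance, each arrival must not
# precede the previous one; violating picks are re-searched after it, and
# excluded when no later crossing exists. `dists` is a named vector of
# expected footstep-to-sensor distances (truth during calibration, search
# region centre during localization); when NULL, picks are taken
# independently and the ordering check is skipped.
pick_arrivals <- function(ep, t_strike, dists = NULL, v_max = 300) {
  envs <- ep$envs
  time <- ep$time
  thresholds <- ep$thresholds
  ord <- if (is.null(dists)) names(envs) else names(sort(dists))
  arr <- setNames(rep(NA_real_, length(ord)), ord)
  floor_t <- -Inf
  prev_d <- NA_real_
  refine <- function(s, a, lo_time) {
    # back-refine the smoothed crossing to the raw rectified onset within
    # one smoothing window (rejects the smoothing-induced delay), never
    # crossing below the ordering lower bound
    if (is.na(a) || is.null(ep$raw)) return(a)
    i1 <- which.min(abs(time - a))
    i0 <- max(1L, i1 - ep$smooth_k)
    if (is.finite(lo_time)) i0 <- max(i0, which.min(abs(time - lo_time)))
    hit <- which(ep$raw[[s]][i0:i1] > ep$thresholds_raw[[s]])[1]
    if (is.na(hit)) a else time[i0 + hit - 1L]
  }
  for (s in ord) {
    lag_min <- if (!is.null(dists) && is.finite(floor_t))
      (dists[[s]] - prev_d) / v_max else 0
    bound <- if (is.finite(floor_t)) floor_t + lag_min else -Inf
    a <- estimate_arrival_time(envs[[s]], time, t_strike,
                               threshold = thresholds[[s]])
    if (!is.null(dists) && !is.na(a) && a < bound) {
      a <- estimate_arrival_time(envs[[s]], time, t_strike,
                                 threshold = thresholds[[s]],
                                 not_before = bound)
    }
    a <- refine(s, a, bound)
    arr[s] <- a
    if (!is.null(dists) && !is.na(a)) {
      floor_t <- a
      prev_d <- dists[[s]]
    }
  }
  arr <- arr[!is.na(arr)]
  if (length(arr) == 0) return(NULL)
  arr <- sort(arr)
  anchor <- names(arr)[1]   # earliest usable sensor: best SNR anchor
  structure(list(arrival = arr, anchor = anchor), class = "arrival_set")
}

#' Localize one footstep by TDoA grid search
#'
#' Over a rectangular grid of candidate locations, the predicted
#' time-difference-of-arrival of sensor k relative to the anchor is
#' `(d_k(p) - d_anchor(p)) / v(x_p)`; the candidate minimizing the summed
#' absolute TDoA misfit is returned (ties broken towards the region centre).
#' Adding a common constant to all arrivals leaves the estimate unchanged.
#'
#' @param arrivals either an `arrival_set` or a named numeric vector of
#'   arrival times (first entry taken as anchor).
#' @param layout a [sensor_layout()].
#' @param profile a [velocity_profile()].
#' @param search_region `c(x_min, x_max, y_min, y_max)` in metres.
#' @param grid_m grid resolution in metres (default 0.05).
#' @return list of class `footstep_location`: `x`, `y`, `residual`
#'   (summed TDoA misfit in seconds).
#' @export
localize_footstep <- function(arrivals, layout, profile, search_region,
                              grid_m = 0.05) {
  if (inherits(arrivals, "arrival_set")) {
    arr <- arrivals$arrival
    anchor <- arrivals$anchor
  } else {
    arr <- arrivals
    anchor <- names(arr)[1]
  }
  if (length(arr) < 3)
    stop("localization requires at least three sensors", call. = FALSE)
  if (search_region[1] > search_region[2] ||
      search_region[3] > search_region[4])
    stop("empty search region", call. = FALSE)
  others <- setdiff(names(arr), anchor)
  obs <- arr[others] - arr[anchor]

  xs <- seq(search_region[1], search_region[2], by = grid_m)
  ys <- seq(search_region[3], search_region[4], by = grid_m)
  cand <- expand.grid(x = xs, y = ys)
  la <- layout[match(c(anchor, others), layout$sensor), ]
  d <- sqrt(outer(cand$x, la$x, `-`)^2 + outer(cand$y, la$y, `-`)^2)
  v <- predict(profile, cand$x)
  pred <- (d[, -1, drop = FALSE] - d[, 1]) / v
  resid <- rowSums(abs(sweep(pred, 2, as.numeric(obs))))
  best <- which(resid <= min(resid) + 1e-15)
  if (length(best) > 1) {
    ctr <- c(mean(search_region[1:2]), mean(search_region[3:4]))
    best <- best[which.min((cand$x[best] - ctr[1])^2 +
                             (cand$y[best] - ctr[2])^2)]
  }
  structure(list(x = cand$x[best], y = cand$y[best],
                 residual = resid[best]), class = "footstep_location")
}

#' Calibrate the velocity profile from ground-truth footsteps
#'
#' For each calibrated footstep (known location and strike time, e.g. from a
#' temporarily installed camera), each sensor's wave travel time gives a
#' velocity `distance / (arrival - strike)`; the per-footstep velocity is the
#' mean over sensors (the mean over directions is taken as representative),
#' and the quartic profile is fitted to the (x, velocity) samples.
#'
#' @param truth data.frame with columns `x`, `y`, `t_strike` (>= 6 rows).
#' @param record the spatial-bandwidth [vibration_record()] (lowpassed at
#'   2500 Hz where the sampling rate allows).
#' @param layout a [sensor_layout()].
#' @param quiet_interval noise-only interval for envelope thresholds.
#' @param clamp velocity clamp for the fitted profile.
#' @return a [velocity_profile()].
#' @export
calibrate_from_truth <- function(truth, record, layout,
                                 quiet_interval = NULL, clamp = c(30, 300)) {
  if (nrow(truth) < 6)
    stop("need at least 6 calibrated footsteps", call. = FALSE)
  check_layout_record(record, layout)
  ep <- envelope_pack(record, quiet_interval %||%
                        c(rec_times(record)[1], truth$t_strike[1] - 0.3))
  xs <- numeric(0); vs <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    d <- layout_distances(layout, truth$x[i], truth$y[i])
    aset <- pick_arrivals(ep, truth$t_strike[i], d)
    if (is.null(aset)) next
    tt <- aset$arrival - truth$t_strike[i]
    valid <- tt > 0
    if (!any(valid)) {
      warning(sprintf("footstep %d skipped: non-positive travel times", i))
      next
    }
    v_i <- mean(d[names(tt)[valid]] / tt[valid])
    xs <- c(xs, truth$x[i]); vs <- c(vs, v_i)
  }
  if (length(xs) < 6)
    stop("fewer than 6 usable calibration footsteps", call. = FALSE)
  fit_velocity_profile(xs, vs, clamp = clamp)
}

# Precompute per-channel arrival-picking series plus noise thresholds
# (mean + 3 sd over the quiet interval). The wave arrival is carried by the
# higher-frequency component of the contact transient, so each channel is
# restricted to the band above the floor's natural-frequency range
# (highpass_hz) and below the spatial lowpass, with CAUSAL filters: a causal
# highpass passes a sharp onset instantly, whereas zero-phase filtering (and
# the analytic envelope) smear energy acausally and bias first-crossing
# picks early. The series is the rectified filtered signal.
envelope_pack <- function(record, quiet_interval, cutoff_hz = 2500,
                          highpass_hz = 60) {
  fs <- record$sample_rate
  hp <- signal::butter(4, highpass_hz / (fs / 2), type = "high")
  lp <- if (cutoff_hz < fs / 2) signal::butter(4, cutoff_hz / (fs / 2),
                                               type = "low") else NULL
  tm <- rec_times(record)
  k <- max(3L, round(0.002 * fs))  # 2 ms causal smoothing of the rectified
  raw <- lapply(setNames(nm = rec_sensors(record)), function(ch) {
    y <- signal::filter(hp, record$samples[, ch])
    if (!is.null(lp)) y <- signal::filter(lp, y)
    abs(as.numeric(y))
  })
  envs <- lapply(raw, function(r) {
    sm <- as.numeric(stats::filter(r, rep(1 / k, k), sides = 1,
                                   method = "convolution"))
    sm[is.na(sm)] <- 0
    sm
  })
  qi <- which(tm >= quiet_interval[1] & tm <= quiet_interval[2])
  if (length(qi) < 10) qi <- seq_len(min(length(tm), 100L))
  thresholds <- lapply(envs, function(e) mean(e[qi]) + 3 * sd(e[qi]))
  thresholds_raw <- lapply(raw, function(e) mean(e[qi]) + 3 * sd(e[qi]))
  list(envs = envs, raw = raw, time = tm, thresholds = thresholds,
       thresholds_raw = thresholds_raw, smooth_k = k)
}

#' Walking-trajectory segment through three footsteps
#'
#' The local trajectory through footsteps `(x1,y1), (x2,y2), (x3,y3)` is the
#' line `y = k x + b` with `k = (y1 - y3) / (x1 - x3)` and
#' `b = (y1 + y2)/2 - k (x1 + x2)/2` (the line through the two midpoints of
#' adjacent footsteps). Near-vertical configurations fall back to the
#' axis-swapped form `x = k y + b`.
#'
#' @param pts 3x2 numeric matrix (rows = consecutive footsteps).
#' @return list of class `trajectory_segment`: `k`, `b`, `swapped`.
#' @export
fit_trajectory <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(nrow(pts) == 3, ncol(pts) == 2)
  if (abs(pts[1, 1] - pts[3, 1]) < 1e-9) {
    pts <- pts[, 2:1]
    swapped <- TRUE
  } else swapped <- FALSE
  k <- (pts[1, 2] - pts[3, 2]) / (pts[1, 1] - pts[3, 1])
  b <- (pts[1, 2] + pts[2, 2]) / 2 - k * (pts[1, 1] + pts[2, 1]) / 2
  structure(list(k = k, b = b, swapped = swapped),
            class = "trajectory_segment")
}

# Point on the segment line and its unit direction, in original coordinates.
segment_frame <- function(seg) {
  a <- c(0, seg$b)
  u <- c(1, seg$k) / sqrt(1 + seg$k^2)
  if (seg$swapped) {
    a <- rev(a)
    u <- rev(u)
  }
  list(a = a, u = u)
}

# Perpendicular distance from point p to the segment line.
segment_distance <- function(seg, p) {
  fr <- segment_frame(seg)
  w <- p - fr$a
  abs(w[1] * fr$u[2] - w[2] * fr$u[1])
}

#' Spatial gait parameters from footstep locations
#'
#' For footstep i (needing neighbours on both sides), the local trajectory is
#' the [fit_trajectory()] segment through footsteps i-1, i, i+1. The step
#' width `w_i` is the perpendicular distance from footstep i to that line;
#' the step length `l_i` is the distance between the projections onto it of
#' the midpoints of footsteps (i-1, i) and (i, i+1); the step angle is
#' `atan(w_i / l_i)` in degrees; the stride length is `s_i = l_i + l_{i+1}`.
#' For collinear footsteps, `l` reduces to the inter-footstep spacing and
#' `w = 0`.
#'
#' @param locations data.frame or matrix with columns `x`, `y` of consecutive
#'   footstep locations (>= 3 rows).
#' @return data.frame: `step`, `x`, `y`, `step_length`, `step_width`,
#'   `step_angle` (degrees), `stride_length` (`NA` where undefined at trace
#'   boundaries).
#' @export
compute_spatial_params <- function(locations) {
  locations <- as.data.frame(locations)
  n <- nrow(locations)
  if (n < 3) stop("need at least 3 localized footsteps", call. = FALSE)
  P <- cbind(locations$x, locations$y)
  l <- w <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    seg <- fit_trajectory(P[(i - 1):(i + 1), ])
    fr <- segment_frame(seg)
    w[i] <- segment_distance(seg, P[i, ])
    m1 <- (P[i - 1, ] + P[i, ]) / 2
    m2 <- (P[i, ] + P[i + 1, ]) / 2
    l[i] <- abs(sum((m2 - m1) * fr$u))
  }
  theta <- ifelse(l > 0, atan2(w, l) * 180 / pi,
                  ifelse(w > 0, 90, 0))
  s <- c(l[-1] + l[-n], NA_real_)
  s[is.na(l)] <- NA_real_
  data.frame(step = seq_len(n), x = locations$x, y = locations$y,
             step_length = l, step_width = w, step_angle = theta,
             stride_length = s)
}

#' Velocity estimation without camera calibration
#'
#' When no ground-truth calibration is available, each footstep's wave
#' propagation velocity is found by scanning candidate velocities over the
#' clamp range and choosing the one that minimizes the area of possible
#' footstep locations: for each v, the TDoA hyperbola bands of the anchor and
#' its three nearest co-recording sensors (half-width one sample period plus
#' the grid-quantisation allowance) are intersected on the localization grid,
#' and the candidate v with the smallest non-empty intersection wins. The
#' surviving (x, v) samples feed [fit_velocity_profile()].
#'
#' @param arrival_sets list of `arrival_set` objects (one per footstep, from
#'   [pick_arrivals()] or constructed from named arrival vectors).
#' @param layout a [sensor_layout()].
#' @param search_regions list of `c(x_min, x_max, y_min, y_max)` per footstep.
#' @param sample_rate record sampling rate (sets the band half-width).
#' @param grid_m localization grid (default 0.05 m).
#' @param clamp velocity scan range (default 30-300 m/s).
#' @param v_step velocity scan step in m/s.
#' @return list: `samples` (data.frame `x`, `y`, `v` per usable footstep) and
#'   `profile` (a [velocity_profile()], or `NULL` when fewer than 6 usable
#'   footsteps).
#' @export
localize_without_calibration <- function(arrival_sets, layout,
                                         search_regions, sample_rate,
                                         grid_m = 0.05, clamp = c(30, 300),
                                         v_step = 5) {
  vs_scan <- seq(clamp[1], clamp[2], by = v_step)
  out <- data.frame(x = numeric(), y = numeric(), v = numeric())
  for (j in seq_along(arrival_sets)) {
    aset <- arrival_sets[[j]]
    if (is.null(aset) || length(aset$arrival) < 3) next
    region <- search_regions[[j]]
    arr <- sort(aset$arrival)
    anchor <- names(arr)[1]
    others <- head(setdiff(names(arr), anchor), 3)
    obs <- arr[others] - arr[anchor]
    xs <- seq(region[1], region[2], by = grid_m)
    ys <- seq(region[3], region[4], by = grid_m)
    cand <- expand.grid(x = xs, y = ys)
    la <- layout[match(c(anchor, others), layout$sensor), ]
    d <- sqrt(outer(cand$x, la$x, `-`)^2 + outer(cand$y, la$y, `-`)^2)
    dd <- d[, -1, drop = FALSE] - d[, 1]

    best <- NULL
    for (v in vs_scan) {
      tol <- 1 / sample_rate + grid_m * sqrt(2) / (2 * v)
      mis <- abs(sweep(dd / v, 2, as.numeric(obs)))
      feas <- rowSums(mis <= tol) == ncol(mis)
      area <- sum(feas) * grid_m^2
      if (area > 0 && (is.null(best) || area < best$area)) {
        ridx <- which(feas)
        loc <- ridx[which.min(rowSums(mis[ridx, , drop = FALSE]))]
        best <- list(area = area, v = v, x = cand$x[loc], y = cand$y[loc])
      }
    }
    if (is.null(best)) {
      warning(sprintf("footstep %d unlocalizable at any velocity in range", j))
      next
    }
    out <- rbind(out, data.frame(x = best$x, y = best$y, v = best$v))
  }
  profile <- if (nrow(out) >= 6)
    tryCatch(fit_velocity_profile(out$x, out$v, clamp = clamp),
             error = function(e) NULL)
  else NULL
  list(samples = out, profile = profile)
}

#' Floor-adaptive spatial parameter estimation
#'
#' Full spatial pipeline for one trace: per-channel envelope picking of wave
#' arrivals after each foot strike, TDoA grid-search localization under the
#' velocity profile (calibrated, supplied, or estimated without calibration),
#' and the step length/width/angle/stride geometry. The search region for
#' each footstep is a prior box ahead of the previous estimate (mean step
#' length +/- 3 sd along x); the first footstep searches the whole walkway
#' band.
#'
#' @param record the spatial-bandwidth [vibration_record()].
#' @param layout a [sensor_layout()] (>= 3 sensors).
#' @param strike_times foot-strike times from the temporal stage.
#' @param profile optional [velocity_profile()]; estimated by
#'   [localize_without_calibration()] when `NULL`.
#' @param quiet_interval noise-only interval for envelope thresholds.
#' @param step_prior `c(mean, sd)` prior on step length in metres for the
#'   search box.
#' @param lateral_halfwidth half-width of the lateral search band in metres.
#' @param grid_m localization grid.
#' @return list: `locations` (data.frame `step`, `x`, `y`, `residual`),
#'   `params` ([compute_spatial_params()] output), `profile`.
#' @export
estimate_spatial <- function(record, layout, strike_times, profile = NULL,
                             quiet_interval = NULL,
                             step_prior = c(0.65, 0.1),
                             lateral_halfwidth = 0.6, grid_m = 0.05) {
  if (nrow(layout) < 3)
    stop("spatial estimation requires at least three sensors", call. = FALSE)
  check_layout_record(record, layout)
  n <- length(strike_times)
  ep <- envelope_pack(record, quiet_interval %||%
                        c(rec_times(record)[1], strike_times[1] - 0.3))
  x_span <- range(layout$x) + c(-1, 1)

  regions <- vector("list", n)
  arrival_sets <- vector("list", n)
  box <- function(prev) {
    if (is.null(prev)) c(x_span[1], x_span[2],
                         -lateral_halfwidth, lateral_halfwidth)
    else c(prev[1] + step_prior[1] - 3 * step_prior[2],
           prev[1] + step_prior[1] + 3 * step_prior[2],
           prev[2] - lateral_halfwidth, prev[2] + lateral_halfwidth)
  }
  # first pass: order-free arrival picks; the anchor (earliest arrival) marks
  # the nearest sensor, anchoring a coarse per-footstep search region
  for (i in seq_len(n)) {
    aset <- pick_arrivals(ep, strike_times[i])
    arrival_sets[[i]] <- aset
    ax <- if (!is.null(aset)) layout$x[match(aset$anchor, layout$sensor)]
          else mean(x_span)
    regions[[i]] <- c(max(x_span[1], ax - 1.5), min(x_span[2], ax + 1.5),
                      -lateral_halfwidth, lateral_halfwidth)
  }
  if (is.null(profile)) {
    uc <- localize_without_calibration(arrival_sets, layout, regions,
                                       record$sample_rate, grid_m = grid_m)
    profile <- uc$profile
    if (is.null(profile) && nrow(uc$samples) > 0)
      profile <- velocity_profile(c(mean(uc$samples$v), 0, 0, 0, 0),
                                  valid_range = x_span)
    if (is.null(profile))
      stop("could not estimate a velocity profile without calibration",
           call. = FALSE)
  }

  # second pass: localization with the profile, advancing the prior box
  loc <- data.frame(step = integer(), x = numeric(), y = numeric(),
                    residual = numeric())
  prev <- NULL
  for (i in seq_len(n)) {
    # before any footstep is localized, fall back to the anchor-sensor
    # region from the first pass (the earliest-arrival sensor is nearest)
    region <- if (is.null(prev)) regions[[i]] else box(prev)
    ctr <- c(mean(region[1:2]), mean(region[3:4]))
    d <- layout_distances(layout, ctr[1], ctr[2])
    aset <- pick_arrivals(ep, strike_times[i], d)
    if (is.null(aset) || length(aset$arrival) < 3) next
    fl <- localize_footstep(aset, layout, profile, region, grid_m = grid_m)
    loc <- rbind(loc, data.frame(step = i, x = fl$x, y = fl$y,
                                 residual = fl$residual))
    prev <- c(fl$x, fl$y)
  }
  params <- if (nrow(loc) >= 3)
    compute_spatial_params(loc[, c("x", "y")])
  else NULL
  if (!is.null(params)) params$step <- loc$step
  list(locations = loc, params = params, profile = profile)
}
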