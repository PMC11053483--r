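test_that("gait cycles pair consecutive footsteps", {
  ev <- data.frame(step = 1:5, side = rep(c("A", "B"), length.out = 5),
                   peak_time = seq(0, 2.2, length.out = 5))
  cyc <- segment_cycles(ev)
  expect_equal(nrow(cyc), 4)
  expect_equal(nrow(segment_cycles(ev[1:3, ])), 2)
  expect_identical(cyc$side, ev$side[1:4])
  expect_true(all(diff(cyc$t_start) > 0))
  expect_error(segment_cycles(ev[1:2, ]), "at least 3")
})

test_that("temporal parameters match the duration definitions exactly", {
  ts <- c(0.0, 0.55, 1.10, 1.65)
  to <- c(0.70, 1.25, 1.80, 2.35)
  p <- compute_temporal_params(data.frame(t_strike = ts, t_off = to))
  i <- 2
  expect_equal(p$step_time[i], 0.55)
  expect_equal(p$stride_time[i], 1.10)
  expect_equal(p$stance_time[i], 0.70)
  expect_equal(p$swing_time[i], 0.40)
  expect_equal(p$double_support1[i], 0.15)
  expect_equal(p$single_support[i], 0.40)
  expect_equal(p$double_support2[i], to[2] - ts[3])
  # boundary cycles are NA, not zero-filled
  expect_true(is.na(p$stride_time[4]))
  expect_true(is.na(p$double_support1[1]))

  # perfectly periodic events give identical parameters for inner cycles
  tsp <- seq(0, 3, by = 0.5)
  top <- tsp + 0.65
  pp <- compute_temporal_params(data.frame(t_strike = tsp, t_off = top))
  expect_equal(sd(pp$step_time, na.rm = TRUE), 0)
  expect_equal(sd(pp$stance_time, na.rm = TRUE), 0)

  expect_error(compute_temporal_params(
    data.frame(t_strike = c(1, 0.5), t_off = c(2, 2))), "increasing")
  expect_error(compute_temporal_params(
    data.frame(t_strike = c(0, 1), t_off = c(-1, 2))), "follow")
})

test_that("temporal identities hold on randomly generated valid cycles", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    steps <- runif(n, 0.4, 0.8)
    ts <- cumsum(c(0, steps[-1]))
    stance_f <- runif(1, 0.55, 0.7)
    stride <- c(ts[3:n] - ts[seq_len(n - 2)], rep(mean(steps) * 2, 2))
    to <- ts + stance_f * stride
    p <- compute_temporal_params(data.frame(t_strike = ts, t_off = to))
    k <- seq_len(n - 2)
    expect_lt(max(abs(p$step_time[k] + p$step_time[k + 1] -
                        p$stride_time[k])), 1e-12)
    expect_lt(max(abs(p$stance_time[k] + p$swing_time[k] -
                        p$stride_time[k])), 1e-12)
    k2 <- 2:(n - 2)
    expect_lt(max(abs(p$single_support[k2] - p$swing_time[k2 - 1]),
                  na.rm = TRUE), 1e-12)
    expect_lt(max(abs(p$double_support1[k2] + p$single_support[k2] -
                        p$step_time[k2])), 1e-12)
  }
})

test_that("strike onset picking follows the reverse-window rule", {
  t <- seq(0, 4, by = 0.001)
  # quiet, then a rise starting at 1.0 peaking at 1.2
  series <- pmax(0, pmin((t - 1) / 0.2, 1)) * exp(-pmax(t - 1.2, 0) / 0.3)
  ts <- detect_strike_time(series, t, c(0.5, 1.5), threshold = 0.02,
                           onset_frac = NULL)
  expect_gte(ts, 0.98)
  expect_lte(ts, 1.05)
  # half-rise refinement sits mid-edge
  ts_half <- detect_strike_time(series, t, c(0.5, 1.5), threshold = 0.02,
                                onset_frac = 0.5)
  expect_equal(ts_half, 1.1, tolerance = 0.01)

  # monotone rise from the window start: onset at the window start
  ramp <- (t - t[1]) / max(t)
  expect_equal(detect_strike_time(ramp, t, c(1, 2), threshold = 0,
                                  onset_frac = NULL), 1, tolerance = 2e-3)

  # time equivariance: shifting the series shifts the estimate
  ts_shift <- detect_strike_time(series, t + 2, c(2.5, 3.5), threshold = 0.02,
                                 onset_frac = NULL)
  expect_equal(ts_shift, ts + 2, tolerance = 1e-9)

  # no peak above the threshold
  expect_true(is.na(detect_strike_time(series * 0, t, c(0.5, 1.5),
                                       threshold = 0.5)))
})

test_that("foot-off picking takes the earliest in-window maximum", {
  t <- seq(0, 2, by = 0.001)
  series <- numeric(length(t))
  series[t >= 0.8 & t <= 0.9] <- 1    # plateau: tie broken earliest
  expect_equal(detect_off_time(series, t, c(0.5, 1.5), threshold = 0.1), 0.8)
  expect_true(is.na(detect_off_time(series * 0, t, c(0.5, 1.5),
                                    threshold = 0.1)))
  expect_equal(detect_off_time(series, t + 1, c(1.5, 2.5), threshold = 0.1),
               1.8)
})

test_that("band extraction finds constructed strike and off tones", {
  # synthetic record: bursts of an 80 Hz tone at the cycle starts and
  # 15 Hz tone at 60% of each cycle
  fs <- 1000
  cyc <- 1.2
  strikes <- 3 + cyc / 2 * (0:7)
  t <- (0:(10 * fs)) / fs
  x <- numeric(length(t))
  for (s in strikes[seq(1, 8, by = 1)]) {
    sel <- t >= s & t <= s + 0.08
    x[sel] <- x[sel] + sin(2 * pi * 80 * t[sel])
    sel2 <- t >= s + 0.62 * cyc & t <= s + 0.68 * cyc
    x[sel2] <- x[sel2] + 1.5 * sin(2 * pi * 15 * t[sel2])
  }
  rec <- vibration_record(matrix(x, ncol = 1, dimnames = list(NULL, "S1")),
                          fs)
  ev <- data.frame(step = seq_along(strikes),
                   side = rep(c("A", "B"), 4),
                   peak_time = strikes)
  sp <- vibragait:::analysis_spectrum(rec)
  bands <- extract_floor_bands(sp, ev)
  expect_true(bands$strike_band[1] <= 80 && 80 <= bands$strike_band[2])
  expect_true(bands$off_band[1] <= 15 && 15 <= bands$off_band[2])
  expect_gt(mean(bands$strike_band), mean(bands$off_band))
})

test_that("extracted bands are floor-specific and stable across seeds", {
  w1 <- analysed_walk(seed = 3, floor_type = "concrete")
  w2 <- analysed_walk(seed = 4, floor_type = "concrete")
  expect_lte(max(abs(w1$tempo$bands$strike_band -
                       w2$tempo$bands$strike_band)), 2.5)
  expect_lte(max(abs(w1$tempo$bands$off_band -
                       w2$tempo$bands$off_band)), 2.5)

  wd <- analysed_walk(seed = 3, floor_type = "wood")
  expect_gt(mean(w1$tempo$bands$strike_band),
            mean(wd$tempo$bands$strike_band))
  expect_gt(mean(w1$tempo$bands$off_band), mean(wd$tempo$bands$off_band))
})

test_that("strike and off times are recovered from simulated walks", {
  for (fl in c("concrete", "wood")) {
    w <- analysed_walk(seed = 5, floor_type = fl)
    err <- timing_errors(w$tempo$cycles, w$truth)
    expect_gte(nrow(err), 8)
    expect_lt(rmse(err$strike), 0.03)
    expect_lt(rmse(err$off), 0.05)
    expect_lt(rmse(err$stance_time), 0.05)
    expect_lt(rmse(err$swing_time), 0.05)
  }
})
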