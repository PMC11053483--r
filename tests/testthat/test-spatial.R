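test_that("quartic velocity-profile fitting recovers known profiles", {
  x <- seq(0, 6, length.out = 12)
  p_const <- fit_velocity_profile(x, rep(100, 12))
  expect_equal(p_const$coefficients[1], 100, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(abs(p_const$coefficients[-1]) < 1e-6))

  p_lin <- fit_velocity_profile(x, 100 + 10 * x)
  expect_equal(unname(p_lin$coefficients[1:2]), c(100, 10),
               tolerance = 1e-6)
  expect_true(all(abs(p_lin$coefficients[3:5]) < 1e-6))

  # nearest-boundary extrapolation and the velocity clamp
  expect_equal(predict(p_lin, 100), predict(p_lin, 6))
  p_fast <- velocity_profile(c(500, 0, 0, 0, 0), valid_range = c(0, 5))
  expect_equal(predict(p_fast, 2), 300)
  p_slow <- velocity_profile(c(5, 0, 0, 0, 0), valid_range = c(0, 5))
  expect_equal(predict(p_slow, 2), 30)

  expect_error(fit_velocity_profile(x[1:4], rep(1, 4)), "at least 6")
  expect_error(fit_velocity_profile(rep(1, 8), rnorm(8)), "degenerate")
})

test_that("TDoA grid search localizes footsteps", {
  lay <- sensor_layout(paste0("S", 1:4), x = c(0, 2, 0, 2), y = c(0, 0, 2, 2))
  vp <- velocity_profile(c(100, 0, 0, 0, 0), valid_range = c(-1, 3))

  # symmetric arrivals: the centre of the square
  arr_eq <- setNames(rep(1, 4), lay$sensor)
  loc <- localize_footstep(arr_eq, lay, vp, c(0, 2, 0, 2))
  expect_equal(c(loc$x, loc$y), c(1, 1))

  # forward-model inversion: exact arrivals for a known location
  pt <- c(1.2, 0.4)
  d <- sqrt((lay$x - pt[1])^2 + (lay$y - pt[2])^2)
  arr <- setNames(5 + d / 100, lay$sensor)
  loc2 <- localize_footstep(arr, lay, vp, c(0, 2.5, -0.5, 2), grid_m = 0.05)
  expect_lte(abs(loc2$x - pt[1]), 0.05)
  expect_lte(abs(loc2$y - pt[2]), 0.05)

  # invariance to a common arrival-time offset
  loc3 <- localize_footstep(arr + 7, lay, vp, c(0, 2.5, -0.5, 2))
  expect_equal(c(loc3$x, loc3$y), c(loc2$x, loc2$y))

  expect_error(localize_footstep(arr[1:2], lay, vp, c(0, 2, 0, 2)),
               "three sensors")
  expect_error(localize_footstep(arr, lay, vp, c(2, 0, 0, 2)), "empty")
})

test_that("trajectory segments follow the midpoint line construction", {
  seg <- fit_trajectory(rbind(c(0, 0), c(1, 0.2), c(2, 0)))
  expect_equal(seg$k, 0)
  expect_equal(seg$b, 0.1)

  seg2 <- fit_trajectory(rbind(c(0, 0), c(1, 0.5), c(2, 1)))
  expect_equal(seg2$k, 0.5)
  expect_equal(seg2$b, 0)

  # affine equivariance: translation maps b -> b + dy - k dx
  pts <- rbind(c(0.3, 0.1), c(0.9, -0.2), c(1.7, 0.15))
  s0 <- fit_trajectory(pts)
  s1 <- fit_trajectory(sweep(pts, 2, c(2, 3), `+`))
  expect_equal(s1$k, s0$k)
  expect_equal(s1$b, s0$b + 3 - s0$k * 2)

  sv <- fit_trajectory(rbind(c(1, 0), c(1.0000000001, 1), c(1, 2)))
  expect_true(sv$swapped)
})

test_that("step geometry matches the hand-worked degenerate cases", {
  collinear <- data.frame(x = c(0, 0.6, 1.2, 1.8), y = rep(0, 4))
  p <- compute_spatial_params(collinear)
  expect_equal(p$step_length[2:3], c(0.6, 0.6))
  expect_equal(p$step_width[2:3], c(0, 0))
  expect_equal(p$step_angle[2:3], c(0, 0))
  expect_equal(p$stride_length[2], 1.2)

  zig <- data.frame(x = c(0, 0.6, 1.2, 1.8),
                    y = c(-0.05, 0.05, -0.05, 0.05))
  pz <- compute_spatial_params(zig)
  expect_equal(pz$step_width[2:3], c(0.05, 0.05), tolerance = 1e-12)
  expect_equal(pz$step_length[2:3], c(0.6, 0.6), tolerance = 1e-12)
  expect_equal(pz$step_angle[2], atan2(0.05, 0.6) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(pz$stride_length[2], pz$step_length[2] + pz$step_length[3])

  # similarity scaling doubles lengths, keeps angles
  p2 <- compute_spatial_params(zig * 2)
  expect_equal(p2$step_length, 2 * pz$step_length)
  expect_equal(p2$step_width, 2 * pz$step_width)
  expect_equal(p2$step_angle, pz$step_angle)
})

test_that("step geometry agrees with the independent oracle", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(4:9, 1)
    P <- data.frame(x = cumsum(runif(n, 0.4, 0.8)),
                    y = rnorm(n, 0, 0.08))
    ours <- compute_spatial_params(P)
    ref <- oracle_spatial_params(P)
    for (col in c("step_length", "step_width", "step_angle",
                  "stride_length")) {
      expect_lt(max(abs(ours[[col]] - ref[[col]]), na.rm = TRUE), 1e-9)
    }
  }
})

test_that("wave arrivals are picked between strike and peak", {
  fs <- 5000
  lay2 <- sensor_layout(c("A", "B", "C"), x = c(2, 2, 4), y = c(0, 0, 0))
  fl <- floor_model(list(floor_mode(20, 0.18, 1),
                         floor_mode(130, 0.08, 12)),
                    velocity = 100, attenuation_rate = 0.5)
  truth1 <- data.frame(step = 1L, side = "A", t_strike = 1, t_off = 1.7,
                       x = 0, y = 0, contact_type = "heel",
                       stringsAsFactors = FALSE)
  rec <- simulate_record(fl, truth1, lay2, fs, duration = 3)
  ep <- vibragait:::envelope_pack(rec, c(0, 0.9))
  d <- vibragait:::layout_distances(lay2, 0, 0)
  aset <- vibragait:::pick_arrivals(ep, 1, d)

  # d = 2 m at v = 100 -> travel 0.02 s, within 2 sample periods
  expect_equal(unname(aset$arrival["A"] - 1), 0.02, tolerance = 2.5 / fs)
  # identical channels give identical arrivals
  expect_equal(unname(aset$arrival["A"]), unname(aset$arrival["B"]))
  # the anchor is the earliest (nearest) usable sensor
  expect_true(aset$anchor %in% c("A", "B"))
})

test_that("camera calibration recovers a constant velocity profile", {
  plan <- walk_plan(n_steps = 10, seed = 2)
  fl <- floor_preset("concrete", velocity = 120)
  sim <- simulate_walk(plan, floor = fl, sample_rate = 5000, snr_db = 30)
  prof <- calibrate_from_truth(
    data.frame(x = sim$truth$x, y = sim$truth$y,
               t_strike = sim$truth$t_strike),
    sim$record, sim$layout)
  v_hat <- predict(prof, seq(0.2, 5.8, length.out = 10))
  # within 5%: the picker crosses the threshold on the wavefront's rise,
  # a small systematic delay that biases velocities slightly low
  expect_true(all(abs(v_hat - 120) / 120 < 0.05))

  expect_error(calibrate_from_truth(
    data.frame(x = sim$truth$x[1:4], y = sim$truth$y[1:4],
               t_strike = sim$truth$t_strike[1:4]),
    sim$record, sim$layout), "at least 6")
})

test_that("velocity is recoverable without calibration by area search", {
  plan <- walk_plan(n_steps = 10, seed = 4)
  fl <- floor_preset("concrete", velocity = 150)
  sim <- simulate_walk(plan, floor = fl, sample_rate = 5000, snr_db = 60)
  ep <- vibragait:::envelope_pack(sim$record, c(0, 2.7))
  asets <- lapply(seq_len(10), function(i) {
    d <- vibragait:::layout_distances(sim$layout, sim$truth$x[i],
                                      sim$truth$y[i])
    vibragait:::pick_arrivals(ep, sim$truth$t_strike[i], d)
  })
  regions <- lapply(seq_len(10), function(i)
    c(sim$truth$x[i] - 0.75, sim$truth$x[i] + 0.75, -0.6, 0.6))
  uc <- localize_without_calibration(asets, sim$layout, regions, 5000)
  expect_gte(mean(abs(uc$samples$v - 150) / 150 <= 0.1), 0.8)
  expect_s3_class(uc$profile, "velocity_profile")

  # invariance to sensor labelling permutation
  perm <- sample(nrow(sim$layout))
  lay_p <- sim$layout[perm, ]
  uc_p <- localize_without_calibration(asets, lay_p, regions, 5000)
  expect_equal(uc_p$samples$v, uc$samples$v)
})
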