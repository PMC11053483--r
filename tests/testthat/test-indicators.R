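test_that("cadence follows the n10 counting identities", {
  ev12 <- data.frame(peak_time = seq(0.4, 9.8, length.out = 12))
  cad <- cadence_from_window(ev12, window_start = 0, trace_end = 10)
  expect_equal(cad$n10, 12)
  expect_equal(cad$step_frequency, 1.2)
  expect_equal(cad$cadence, 72)

  none <- cadence_from_window(data.frame(peak_time = numeric(0)),
                              window_start = 0, trace_end = 10)
  expect_equal(none$cadence, 0)

  ev24 <- data.frame(peak_time = seq(0.2, 9.9, length.out = 24))
  expect_equal(cadence_from_window(ev24, 0, 10)$cadence, 2 * cad$cadence)

  short <- cadence_from_window(ev12, window_start = 0.4, trace_end = 9.8)
  expect_true(short$partial_window)
  expect_equal(short$step_frequency, 11 / (9.8 - 0.4), tolerance = 1e-9)
})

test_that("walking speed is step length over step time", {
  expect_equal(walking_speed(0.5, 0, 0.5), 1)
  expect_equal(walking_speed(0, 0, 0.5), 0)
  expect_equal(walking_speed(0.5, 0, 0.25), 2 * walking_speed(0.5, 0, 0.5))
  expect_error(walking_speed(0.5, 1, 1), "increasing")
})

test_that("the symmetry index has its closed form, bounds and symmetry", {
  expect_equal(symmetry_index(0.6, 0.6)$si, 0)
  expect_equal(symmetry_index(0.60, 0.75)$si, 2 * 0.15 / 1.35)
  expect_equal(symmetry_index(0.60, 0.75)$si, 0.22222, tolerance = 1e-4)
  expect_equal(symmetry_index(0, 1)$si, 2)
  expect_error(symmetry_index(0, 0), "undefined")

  set.seed(4)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    si_ab <- symmetry_index(a, b)$si
    expect_equal(si_ab, symmetry_index(b, a)$si)
    expect_gte(si_ab, 0)
    expect_lte(si_ab, 2)
  }
})

test_that("the balance score is the mean squared relative deviation", {
  expect_equal(balance_score(c(0.4, 0.6))$bs, 0.04)
  expect_equal(balance_score(rep(0.7, 5))$bs, 0)
  x <- c(0.5, 0.62, 0.48, 0.55)
  expect_equal(balance_score(3 * x)$bs, balance_score(x)$bs)
  expect_error(balance_score(0.5), "at least 2")
  expect_error(balance_score(c(-1, 1)), "zero-mean")
})

test_that("normalized energy compensates the simulator's attenuation", {
  expect_equal(normalized_energy(c(1, 2), 0, 0.7), 5)
  expect_equal(normalized_energy(c(1, 2), 3, 0), 5)
  expect_error(normalized_energy(numeric(0), 1, 0.5), "empty")

  # one noiseless footstep seen by sensors at different distances agrees
  # after compensation with alpha = 2 x amplitude attenuation rate
  fl <- floor_preset("concrete")
  lay <- sensor_layout(c("N", "F"), x = c(1, 4), y = c(0, 0))
  truth1 <- data.frame(step = 1L, side = "A", t_strike = 0.5, t_off = 1.2,
                       x = 0, y = 0, contact_type = "heel",
                       stringsAsFactors = FALSE)
  rec <- simulate_record(fl, truth1, lay, 1000, duration = 2.5)
  dn <- 1; df <- 4
  en <- normalized_energy(rec$samples[, "N"], dn, 2 * fl$attenuation_rate)
  ef <- normalized_energy(rec$samples[, "F"], df, 2 * fl$attenuation_rate)
  expect_lt(abs(en - ef) / en, 0.1)
})

test_that("contact features are binned, normalized band summaries", {
  fs <- 1000
  t <- (0:1999) / fs
  tone <- sin(2 * pi * 35 * t)
  sp <- morlet_cwt(tone, fs, seq(5, 495, by = 5))
  f <- contact_features(sp, c(0.5, 1.5))
  expect_equal(names(which.max(f)), "bin_30_40")
  expect_equal(sum(f), 1, tolerance = 1e-9)

  zero_sp <- morlet_cwt(numeric(2000), fs, seq(5, 495, by = 5))
  expect_true(all(contact_features(zero_sp, c(0.5, 1.5)) == 0))

  # features of a stationary signal do not depend on the window length
  f1 <- contact_features(sp, c(0.5, 1.0))
  f2 <- contact_features(sp, c(0.5, 1.5))
  expect_equal(f1, f2, tolerance = 0.02)

  expect_error(contact_features(sp, c(0.5, 0.5001)), "too short")
})

test_that("the contact classifier separates and yields probabilities", {
  set.seed(9)
  x <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 4), 20))
  y <- rep(c("a", "b"), each = 20)
  m <- train_contact_classifier(x, y)
  pred <- predict_contact(m, x)
  expect_equal(mean(pred$predicted == y), 1)
  expect_equal(rowSums(as.matrix(pred[, m$classes])), rep(1, 40),
               tolerance = 1e-9)
  expect_error(train_contact_classifier(x, rep("a", 40)), "two contact")

  path <- withr::local_tempfile(fileext = ".rds")
  save_contact_classifier(m, path)
  m2 <- load_contact_classifier(path)
  expect_identical(predict_contact(m2, x)$predicted, pred$predicted)
})

test_that("symmetric zero-variability walks give zero SI and BS", {
  truth <- generate_walk(walk_plan(n_steps = 8, step_length_sd = 0,
                                   step_width_sd = 0, step_time_sd = 0,
                                   left_right_length_ratio = 1))
  p <- compute_temporal_params(data.frame(t_strike = truth$t_strike,
                                          t_off = truth$t_off,
                                          side = truth$side))
  stance_a <- mean(p$stance_time[p$side == "A"], na.rm = TRUE)
  stance_b <- mean(p$stance_time[p$side == "B"], na.rm = TRUE)
  expect_lt(symmetry_index(stance_a, stance_b)$si, 1e-6)
  st <- p$step_time[!is.na(p$step_time)]
  expect_lt(balance_score(st)$bs, 1e-12)
})

test_that("stance-time asymmetry is recovered through the pipeline", {
  # an asymmetric-stance walk: side A stance lengthened via the ratio on
  # estimated stance times grouped by detected parity
  w <- analysed_walk(seed = 6, floor_type = "concrete")
  p <- w$tempo$params
  a <- mean(p$stance_time[p$side == "A"], na.rm = TRUE)
  b <- mean(p$stance_time[p$side == "B"], na.rm = TRUE)
  si_est <- symmetry_index(a, b)$si
  tru <- compute_temporal_params(data.frame(t_strike = w$truth$t_strike,
                                            t_off = w$truth$t_off,
                                            side = w$truth$side))
  ta <- mean(tru$stance_time[tru$side == "A"], na.rm = TRUE)
  tb <- mean(tru$stance_time[tru$side == "B"], na.rm = TRUE)
  expect_lt(abs(si_est - symmetry_index(ta, tb)$si), 0.05)
})
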