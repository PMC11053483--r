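test_that("generate_walk reproduces the scripted gait statistics", {
  plan0 <- walk_plan(n_steps = 5, mean_step_length = 0.6,
                     step_length_sd = 0, step_width_sd = 0, step_time_sd = 0)
  truth <- generate_walk(plan0)
  expect_equal(truth$x, c(0, 0.6, 1.2, 1.8, 2.4))
  expect_identical(truth$side, c("A", "B", "A", "B", "A"))
  expect_true(all(diff(truth$t_strike) > 0))
  expect_true(all(truth$t_off > truth$t_strike))
  # foot-off at the stance fraction of the local stride
  n <- nrow(truth)
  stride <- truth$t_strike[3:n] - truth$t_strike[seq_len(n - 2)]
  expect_equal(truth$t_off[seq_len(n - 2)],
               truth$t_strike[seq_len(n - 2)] + plan0$stance_fraction * stride)

  # determinism: same plan, same seed
  expect_identical(generate_walk(plan0), generate_walk(plan0))

  # Monte-Carlo: sample mean of step lengths within 3 SE of the model mean
  plan_mc <- walk_plan(n_steps = 200, mean_step_length = 0.6,
                       step_length_sd = 0.05, seed = 42)
  tr <- generate_walk(plan_mc)
  lens <- diff(tr$x)
  se <- 0.05 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 0.6), 3 * se)

  # asymmetry ratio scales side-A steps
  plan_r <- walk_plan(n_steps = 400, left_right_length_ratio = 1.2,
                      step_length_sd = 0, seed = 7)
  tr_r <- generate_walk(plan_r)
  lens_r <- diff(tr_r$x)
  side_of_step <- tr_r$side[-1]
  expect_equal(mean(lens_r[side_of_step == "A"]) /
                 mean(lens_r[side_of_step == "B"]), 1.2, tolerance = 1e-9)

  expect_error(walk_plan(n_steps = 2), "n_steps")
  expect_error(walk_plan(stance_fraction = 1.2), "stance_fraction")
})

test_that("footstep force profiles have the contact-type spectral structure", {
  fs <- 1000
  for (type in c("heel", "midfoot", "toe")) {
    f <- make_footstep_force(type, stance_duration = 0.7, sample_rate = fs)
    expect_true(all(f$samples >= 0))
    expect_equal(length(f$samples), round(0.7 * fs))
  }
  expect_error(make_footstep_force("sideways", 0.7), "arg")
  expect_error(make_footstep_force("heel", -1), "stance_duration")

  zero <- make_footstep_force("heel", 0.7, peak_amplitude = 0)
  expect_true(all(zero$samples == 0))

  # impulse (force integral) scales linearly with peak amplitude
  f1 <- make_footstep_force("heel", 0.7, peak_amplitude = 1)
  f3 <- make_footstep_force("heel", 0.7, peak_amplitude = 3)
  expect_equal(sum(f3$samples), 3 * sum(f1$samples), tolerance = 1e-12)

  # spectral orderings: heel has strictly more energy below 30 Hz than toe;
  # midfoot is predominantly low-frequency, toe predominantly high
  spec_energy <- function(x, lo, hi) {
    X <- Mod(fft(c(x, numeric(4096 - length(x)))))^2
    fr <- (seq_along(X) - 1) * fs / length(X)
    sum(X[fr >= lo & fr <= hi])
  }
  heel <- make_footstep_force("heel", 0.7, sample_rate = fs)$samples
  toe <- make_footstep_force("toe", 0.7, sample_rate = fs)$samples
  mid <- make_footstep_force("midfoot", 0.7, sample_rate = fs)$samples
  expect_gt(spec_energy(heel, 0, 30), spec_energy(toe, 0, 30))
  expect_gt(spec_energy(toe, 60, 400) / spec_energy(toe, 0, 30),
            spec_energy(mid, 60, 400) / spec_energy(mid, 0, 30))
  expect_gt(spec_energy(heel, 60, 400), 0.5 * spec_energy(toe, 60, 400))
})

test_that("simulated records follow the modal, delay and attenuation laws", {
  lay2 <- sensor_layout(c("A", "B"), x = c(1, 3), y = c(0, 0))
  one_mode <- floor_model(floor_mode(20, 0.05, 1), velocity = 100,
                          attenuation_rate = 0)
  truth1 <- data.frame(step = 1L, side = "A", t_strike = 0.2, t_off = 0.21,
                       x = 0, y = 0, contact_type = "toe",
                       stringsAsFactors = FALSE)
  rec <- simulate_record(one_mode, truth1, lay2, sample_rate = 1000)

  # empty truth, zero noise -> all-zero record
  empty <- simulate_record(one_mode, truth1[0, ], lay2, sample_rate = 1000)
  expect_true(all(empty$samples == 0))

  # delay law: first-motion difference = (3 - 1) m / 100 m/s = 0.02 s
  onset <- function(ch) rec_times(rec)[which(abs(rec$samples[, ch]) > 0)[1]]
  expect_equal(onset("B") - onset("A"), 0.02, tolerance = 1.01 / 1000)

  # envelope of the free decay falls off as exp(-xi*omega*t)
  tm <- rec_times(rec)
  seg <- tm > 0.28 & tm < 0.55
  env <- envelope(rec$samples[, "A"])
  fit <- lm(log(env[seg]) ~ tm[seg])
  expect_equal(unname(coef(fit)[2]), -0.05 * 2 * pi * 20, tolerance = 0.05)

  # spectral law: dominant frequency = damped modal frequency within a bin
  n <- nrow(rec$samples)
  X <- Mod(fft(rec$samples[, "A"]))[1:(n %/% 2)]
  f_dom <- (which.max(X) - 1) * 1000 / n
  f_damped <- 20 * sqrt(1 - 0.05^2)
  expect_lt(abs(f_dom - f_damped), 1000 / n + 1e-9)

  # linearity: doubling force amplitude doubles the noiseless record
  rec2 <- simulate_record(one_mode, truth1, lay2, sample_rate = 1000,
                          amplitude = 2)
  expect_lt(max(abs(rec2$samples - 2 * rec$samples)) /
              max(abs(rec$samples)), 1e-9)

  # reproducibility: identical seeds give bit-identical noisy records
  na <- simulate_record(one_mode, truth1, lay2, 1000, noise_sd = 0.1,
                        seed = 9)
  nb <- simulate_record(one_mode, truth1, lay2, 1000, noise_sd = 0.1,
                        seed = 9)
  expect_identical(na$samples, nb$samples)

  # validation errors
  out_truth <- truth1
  out_truth$x <- 99
  expect_error(simulate_record(one_mode, out_truth, lay2, 1000), "extent")
  expect_error(simulate_record(one_mode, truth1, lay2, 50), "4x")
})

test_that("floor presets and models validate their parameters", {
  expect_error(floor_mode(-5, 0.1), "frequency")
  expect_error(floor_mode(10, 1.5), "damping")
  expect_error(floor_model(list()), "modes")
  wood <- floor_preset("wood")
  concrete <- floor_preset("concrete")
  expect_gt(predict(concrete$velocity, 3), predict(wood$velocity, 3))
  expect_gt(concrete$attenuation_rate, wood$attenuation_rate)
  f_low <- function(m) min(vapply(m$modes, `[[`, 0, "frequency_hz"))
  expect_lt(f_low(wood), f_low(concrete))
})
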