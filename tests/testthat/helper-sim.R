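# Shared simulation fixtures, built once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# A standard analysed walk: record + truth + detection + temporal estimates.
analysed_walk <- function(seed = 3, floor_type = "concrete", n_steps = 10,
                          snr_db = 20, sample_rate = 1000, ...) {
  key <- paste("walk", seed, floor_type, n_steps, snr_db, sample_rate,
               sep = "_")
  cached(key, {
    plan <- walk_plan(n_steps = n_steps, seed = seed, ...)
    sim <- simulate_walk(plan, floor = floor_preset(floor_type),
                         sample_rate = sample_rate, snr_db = snr_db)
    noise <- estimate_noise_stats(sim$record, c(0, 2.8))
    events <- detect_footsteps(sim$record, noise)
    tempo <- if (nrow(events) >= 5)
      estimate_temporal(sim$record, events) else NULL
    c(sim, list(noise = noise, events = events, tempo = tempo))
  })
}

# Noise-only record on the concrete preset layout.
noise_record <- function(seed = 11, sd = 1, duration = 8, fs = 1000) {
  key <- paste("noise", seed, sd, duration, fs, sep = "_")
  cached(key, {
    set.seed(seed)
    n <- duration * fs
    vibration_record(matrix(rnorm(n * 4, 0, sd), n, 4,
                            dimnames = list(NULL, paste0("S", 1:4))), fs)
  })
}
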