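# vibragait

Quantitative gait analysis from footstep-induced floor vibrations.

When a person walks across a floor, every footstep deflects the structure and
launches vibration waves that floor-mounted sensors (geophones) pick up
metres away. `vibragait` turns such multichannel vibration recordings into
the gait measures used in clinical practice:

- **temporal parameters** — step, stride, stance, swing, single-support and
  double-support times, from per-cycle foot-strike times `t_i^s` and
  foot-off times `t_i^o` (e.g. step time `= t_{i+1}^s − t_i^s`, stance time
  `= t_i^o − t_i^s`);
- **spatial parameters** — step length, step width, step angle
  `θ_i = atan(w_i / l_i)` and stride length `s_i = l_i + l_{i+1}`, from
  footstep locations localized by time-difference-of-arrival (TDoA) grid
  search under a spatially varying wave-velocity profile
  `v(x) = β₀ + β₁x + β₂x² + β₃x³ + β₄x⁴` (clamped to 30–300 m/s);
- **gait-health indicators** — cadence `c = 6·n₁₀` (footsteps per 10 s),
  walking speed `vᵢ = lᵢ / (t_{i+1}^s − t_i^s)`, the absolute symmetry index
  `SI = 2|X_R − X_L| / (X_R + X_L)`, the balance score
  `BS = (1/N) Σ ((Xᵢ − X̄)/X̄)²`, and heel/midfoot/toe initial-contact
  probabilities from an RBF-kernel SVM on 10 Hz frequency-bin features;
- a **personalized gait profile**: per-parameter z-scores against packaged
  population reference means, drawn as a radar chart.

The pipeline is *floor-adaptive*: footsteps are detected by Morlet
continuous-wavelet peak picking in the 5–50 Hz floor natural-frequency band
with noise-adaptive thresholds, and the dominant frequency bands used for
strike/off timing are extracted per floor from the 0–10% and 60–70% phases
of the gait cycle. A physics-based synthetic walk simulator (reduced modal
floor model, heel/midfoot/toe force profiles, propagation delay, distance
attenuation, additive noise) provides exact ground truth for every stage and
drives the whole test suite — no instrumented-walkway data are required.

## Worked example

```r
library(vibragait)

# 1. simulate a ten-step walk on the concrete floor preset at 20 dB SNR
plan <- walk_plan(n_steps = 10, seed = 5)
sim <- simulate_walk(plan, floor = floor_preset("concrete"),
                     sample_rate = 1000, snr_db = 20)

# 2. full pipeline: detection -> temporal -> spatial -> indicators
res <- run_pipeline(sim$record, sim$layout,
                    velocity = sim$floor$velocity,
                    config = list(attenuation_rate = 0.7))

head(res$temporal$params[, c("cycle", "side", "step_time", "stride_time",
                             "stance_time", "swing_time")], 4)
#>   cycle side step_time stride_time stance_time swing_time
#> 1     1    A     0.600       1.210       0.786      0.424
#> 2     2    B     0.610       1.206       0.781      0.425
#> 3     3    A     0.596       1.194       0.775      0.419
#> 4     4    B     0.598       1.173       0.763      0.410

res$indicators$cadence
#> [1] 101.3323
```

The plan drew step times around 0.581 s, so ~0.60 s step times, ~1.2 s
strides and a cadence of ~101 steps/min are the expected recoveries; stance
times near 0.77 s reflect the plan's stance fraction (64.3% of the stride).
The profile then scores each parameter against the packaged reference
cohort:

```r
prof <- build_profile(res)
prof[prof$parameter %in% c("step_time", "step_length", "cadence"),
     c("parameter", "value", "z")]
#>     parameter        value          z
#> 1   step_time   0.59222222  0.2439614
#> 7 step_length   0.76643495  1.4263702
#> 11    cadence 101.33233252 -0.3230992
plot_gait_profile(prof)   # radar chart, z-score rings
```

A z of 0.24 means this walker's step time sits a quarter of a population
standard deviation above the reference mean; values beyond ±2 flag unusual
gait. A command-line interface wrapping the same functions lives at
`inst/cli/vibragait.R` (`simulate`, `analyze`, `profile` subcommands).

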