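---
title: "Floor-vibration gait analysis: models, methods and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floor-vibration gait analysis: models, methods and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibragait)
```

## The sensing problem

A walking person applies a force `F(t)` to the floor at each footstep; the
floor responds according to the structural equation of motion
`M ü + C u̇ + K u = F(t)`, and geophones on the floor surface report the
local vertical *velocity* of that response as a voltage time series. Two
physical facts make gait analysis from these signals possible:

1. **Timing is preserved.** The response at any sensor is (to good
   approximation) a linear time-invariant filtering of the footstep force,
   so gait events — the sharp initial contact (foot strike) and the release
   of the load (foot off) — appear at their true times, merely delayed by
   the wave travel time and coloured by the floor's transfer function.
2. **The colouring is structured.** The transfer function amplifies the
   force spectrum around the floor's modal frequencies. An impulsive foot
   strike excites a broad band including higher local modes; the foot-off
   release rings mainly the fundamental, so the low-frequency (natural
   frequency) component peaks at foot off and then decays as free
   vibration.

The floor's modes and wave speeds differ between buildings — that is the
*floor-adaptation* problem this package addresses: dominant frequency bands
are extracted per floor, and wave velocities are calibrated per walkway.

## The synthetic floor and walk model

Because instrumented-walkway recordings are rarely shareable, the package
carries a forward simulator that generates every fixture used by the tests.

**Floor.** A reduced modal model: each mode `j` contributes
`w_j · exp(−ξ_j ω_j t) · sin(ω_dj t)` to the displacement impulse response;
the simulator uses its time derivative (normalized per mode by `ω_dj`)
because geophones sense velocity. This kills quasi-static content — a
slowly varying body-weight load produces almost no signal — while sharp
transients ring the modes, which is exactly the structure the pipeline
exploits. Wave propagation is pure delay at `v(x_footstep)` plus
exponential amplitude decay `exp(−α·d)`; dispersion is not modelled.

Two presets stand in for common constructions (illustrative values, not
measurements of a particular building): *wood* — modes 12 Hz (ξ = 0.22) and
60 Hz (ξ = 0.09, weight 12), v = 90 m/s, α = 0.4 /m; *concrete* — modes
20 Hz (ξ = 0.18) and 130 Hz (ξ = 0.08, weight 12), v = 180 m/s, α = 0.7 /m.
Each preset pairs one low structural mode (inside the 5–50 Hz detection
band) with one high local/plate mode (the strike signature). Two close low
modes (say 12 and 25 Hz) cannot be resolved by a Morlet analysis whose
frequency spread is `f/6`, so the presets keep the pair far apart; the
heavier damping of the low modes makes the foot-off ring die away within
the double-support interval instead of bleeding into the next event.

**Footstep forces.** Raised-cosine building blocks: a ~6 ms contact
transient of amplitude `A` (broadband, rings the high mode), plus for heel
strikes a body-weight hump (0.45 A) that rises over the first third of
stance and unloads through an end-weighted (quartic) ~80 ms push-off
release whose steepest change falls exactly at foot off — so the
natural-frequency ring it excites peaks at `t^o`, the signature the foot-off
detector uses. Midfoot contacts are a single broad smooth pulse (low
bandwidth, no transient); toe contacts are the transient alone. Only the
spectral *orderings* matter (heel has both low- and high-frequency energy,
toe mostly high, midfoot mostly low); the exact shapes are modelling
choices.

**Walks.** Step lengths, widths and times are independent normals around
plan means; sides alternate; side-A step lengths scale by an asymmetry
ratio. Defaults reproduce a healthy adult reference gait: step length
0.678 m, step time 0.581 s, and stance fraction 0.643 of the stride — the
value that reproduces both the reference stance time (0.747 s) and
double-support time (0.166 s) given the reference step time. Foot-off times
are `t^s + 0.643 ×` the local stride. Records start with a 3 s noise-only
lead-in, the conventional length of a noise segment for threshold and
Wiener-filter estimation. Noise is white Gaussian; `snr_db` is defined
against the mean signal power over the active walking span (an RMS
signal-to-noise ratio). The simulated study conditions are 10-step walks at
20 dB SNR, sampled at 1 kHz for the temporal path and 5 kHz for the spatial
path.

## Detection

Each channel is lowpassed (500 Hz, zero-phase 4th-order Butterworth applied
forward–backward with odd-reflection padding) and transformed with a complex
Morlet CWT (centre frequency parameter 6; scale–frequency conversion by the
exact Fourier factor). Footsteps are peaks of the 5–50 Hz band-summed,
channel-summed magnitude series, smoothed by an 80 ms moving average so
peak prominences are stable against noise; the noise statistics that set
the thresholds (height above mean + 3 sd, prominence above 3 sd of a
noise-only segment) are computed on the same smoothed construction. Peaks
closer than 0.25 s keep only the larger; runs need at least three impulses
with spacings inside [0.25, 2.5] s, and run-edge peaks below 55% of the
run's median above-noise height are trimmed — footsteps repeat in amplitude
as well as rhythm, and that rule removes the one stray event a walk's final
push-off ring would otherwise leave. Sides alternate A/B by parity; true
left/right is unrecoverable from vibrations alone and never needed, because
the symmetry index uses absolute differences.

## Temporal parameters

The wavelet analysis grid starts at 8 Hz (above body-weight-transfer
content). Dominant bands are extracted once per floor from the averaged
magnitude spectrum of two cycle-phase windows — 0–10% of the cycle for
strikes and 60–70% for foot offs, both shifted back slightly because the
detected peak times lag the true strikes by the wavelet time smear. Both
windows contain the fundamental's ring, so the assignment is structural:
the foot-off band (the fundamental) is extracted first and the strike band
is then the dominant interval *above* it, which also enforces the required
ordering (strikes are the higher range). Band edges use the contiguous
interval above 50% of the window maximum.

Foot strikes: on the strike-band series, the peak near each detected event
is walked backwards (one sample at a time) to the first local minimum or
noise-threshold crossing — where the vibration starts to rise — and then
refined to the half-rise point, which centres the estimate under the
wavelet's symmetric time smearing; on the simulated conditions this
recovers strike times to ~10 ms. Foot offs: the earliest maximum of the
off-band series within 60–72% of the measured cycle (the conventional
60–70% foot-off phase of the gait cycle, plus a smear allowance); a window that starts earlier
drifts onto the decaying ring of the opposite strike. Cycles whose off peak
never clears the threshold are flagged and dropped from averages, not
imputed. The six duration parameters follow algebraically and satisfy their
identities (step + step = stride, stance + swing = stride, single-support =
previous swing) to machine precision by construction.

## Spatial parameters

Wave arrivals are picked on the higher-frequency component: each channel is
highpassed above the floor's natural band (60 Hz) and lowpassed at 2500 Hz
with *causal* filters — a causal highpass passes a sharp onset instantly,
whereas zero-phase filtering (or an analytic envelope) smears energy
acausally and biases first-crossing picks early. The pick is the first
crossing of mean + 3 sd that is sustained for 3 ms (brief noise excursions
are rejected), back-refined to the raw rectified onset within the 2 ms
smoothing window. Sensors are processed in order of expected distance; a
pick that precedes the previous sensor's arrival plus the minimum physical
lag (Δd / 300 m/s) is re-searched, and excluded if no later crossing
exists. Because the crossing happens on the wavefront's rise, travel times
carry a ~1 ms systematic delay, which biases calibrated velocities 2–3%
low — visible in the constant-velocity recovery test (asserted at 5%) and
far inside the 10% budget for profile recovery.

Localization is a grid search (0.05 m): the predicted TDoA of sensor `k`
relative to the anchor (earliest usable arrival) at candidate `p` is
`(d_k(p) − d_anchor(p)) / v(x_p)`, and the candidate with the smallest
summed absolute misfit wins (ties to the region centre). The search region
is a prior box ahead of the previous footstep (mean step ± 3 sd; the first
footstep searches ±1.5 m around the anchor sensor). Velocity comes from a
camera-calibrated quartic profile, a user-supplied profile, or the
calibration-free area search: scanning v over 30–300 m/s, intersecting the
TDoA bands (half-width one sample period plus half a grid diagonal) of the
anchor and its three nearest co-recording sensors, and keeping the v with
the smallest non-empty intersection area. With only two TDoA constraints
the (x, y, v) system is underdetermined and the area grows monotonically
with v, so the method needs the fourth sensor; with three constraints it
recovers a constant 150 m/s within 10% for over 80% of footsteps.

Step geometry follows the midpoint-projection construction: the local
trajectory through footsteps i−1, i, i+1 is the line `y = kx + b` with
`k = (y_{i−1} − y_{i+1}) / (x_{i−1} − x_{i+1})` and `b` through the first
midpoint (axis-swapped when near-vertical); the step width is the
perpendicular distance of footstep i to that line, and the step length the
distance between the projections of the two adjacent midpoints — which
reduces exactly to the inter-footstep spacing for collinear steps. The
printed closed form of this projection is easy to mistype, so the test
suite checks the implementation against an independently written
brute-force evaluator on random configurations at 1e−9, and the degenerate
collinear case by hand. Localization errors are biased by the common
velocity assumption, but the bias largely cancels in step *length*
(a difference of adjacent locations), which is why step-length RMSE
(≈0.08 m on the study conditions) beats raw localization accuracy.

## Indicators and profile

Cadence counts footsteps in a 10 s window (`c = 6·n₁₀`); short traces
extrapolate the inter-event rate and are flagged. SI and BS are the
closed-form statistics given in the README; the kinetic measure is signal
energy compensated by `exp(α·d)` on the energy scale (twice the amplitude
attenuation rate). Contact-type features are means of the time-summed
wavelet magnitudes in 10 Hz bins up to 500 Hz, normalized by their total so
classification is amplitude- (hence distance-) invariant; three one-vs-rest
RBF SVMs (cost 1, gamma 1/50 — the e1071 defaults, configurable) provide
margins that a unit-temperature softmax converts to class probabilities.
The gait profile reports per-parameter trace means and z-scores against the
packaged reference cohort (the two double-support measures are averaged
into one parameter). The reference cohort skews slightly towards slower
walking than larger population datasets, a caveat to keep in mind when
reading profiles; the profile of the reference itself is the zero vector.

## What the synthetic tests do and do not show

The simulator reproduces the features the algorithms rely on — modal
ringing, floor-specific bands, arrival delays, attenuation, noise-adaptive
thresholds — and gives exact ground truth, so the suite demonstrates that
the *algorithms* recover what the model encodes: detection recall and
precision 1.0 at 20 dB, strike times to ~10 ms, stance/swing to ~20 ms,
step lengths to ~0.08 m, contact types at ~100% held-out accuracy. Real
recordings add dispersion, dense and irregular modal structure,
non-stationary interference, soft shoes and gait pathologies, none of which
are modelled; the synthetic error figures are therefore lower bounds on
real-world error, not forecasts.

One planned comparison fails for exactly this reason, and is reported
rather than hidden. Analyzing concrete-floor walks with bands extracted
from the wood floor *should* degrade timing (floor adaptation is the point
of band extraction), but in the simulator every frequency band carries a
time-locked copy of the footstep events — resonant rings where there is a
mode, a sharp forced response where there is none — so mismatched bands
time the events about as well as matched ones (strike+off RMSE ≈ 8 ms vs
≈ 11 ms). The mechanisms that punish band mismatch on real floors
(dispersion, modal density, coloured interference) are precisely the ones
the reduced model omits. The acceptance suite asserts the real-world
expectation and the assertion fails; both RMSEs appear in the acceptance
report so the comparison stays visible.

## Numerical choices and degenerate inputs

- Lowpass: 4th-order Butterworth, forward–backward, odd-reflection padding;
  cutoffs 500 Hz (temporal/indicator path) and 2500 Hz (spatial path);
  records above 2 kHz are decimated to ~1 kHz for the temporal path.
- Wiener gain floor 0.05 (avoids musical noise); noise spectra by Welch
  averaging with Hann windows and 50% overlap. A gain computed from the
  record's own spectrum is signal-dependent, so the Wiener stage is not a
  linear filter; linearity holds (and is tested) for the lowpass.
- Morlet ω₀ = 6; analysis grid 2.5 Hz spacing from 8 Hz; detection-series
  smoothing 80 ms.
- Ties: earliest maximum for foot-off; earliest threshold crossing for
  strikes and arrivals; localization ties to the region centre.
- Degenerate inputs error early with the offending field named: fewer than
  three events, bands that do not intersect the grid, quiet intervals
  outside the record, fewer than six calibration footsteps, velocity fits
  with degenerate x spread, localization with fewer than three sensors.
- Zero-length steps, all-zero windows and empty truth tables are exercised
  in the tests and return the documented zeros/empties rather than failing.

## Problem sizes

The default test and acceptance runs use 10-step walks (plus 6-step walks
for the 25-walk detection sweep), 1 kHz temporal and 5 kHz spatial sampling,
20 dB SNR, 600 classifier footsteps and 100 random geometry configurations;
the full acceptance script completes in about a minute on one CPU.
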