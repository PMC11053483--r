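Package: vibragait
Title: Gait Analysis from Footstep-Induced Floor Vibrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spatiotemporal gait parameters and gait-health indicators
    from multichannel floor-vibration recordings of walking. Footstep impulses
    are detected by Morlet continuous-wavelet peak picking with noise-adaptive
    thresholds; floor-adaptive dominant-frequency bands yield foot-strike and
    foot-off times and the six temporal parameters; footsteps are localized by
    time-difference-of-arrival grid search under a spatially varying
    wave-velocity profile, giving step length, width, angle and stride length;
    cadence, walking speed, left-right symmetry indices, balance scores and
    initial-contact-type probabilities summarize gait health against packaged
    population reference values. A physics-based synthetic walk simulator
    (modal floor response, heel/midfoot/toe force profiles, distance
    attenuation and propagation delay) provides exact ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
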