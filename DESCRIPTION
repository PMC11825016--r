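Package: pambaleen
Title: Passive Acoustic Monitoring Pipeline for Baleen Whale Presence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for shelf-scale passive acoustic
    monitoring of baleen whales, exercisable entirely on synthetic data.
    Generates calibrated synthetic soundscapes (vessel-noise-dominated
    ambient sound with injected species calls and ground-truth
    annotations), runs species-specific detectors (spectrogram template
    cross-correlation, waveform matched filtering, upsweep contour
    tracing, band-energy unit detection), evaluates daily-scale detector
    performance (true positive rate), aggregates detections into daily
    presence and season/survey-year summaries, fits a cyclic-seasonal
    Bernoulli presence GAM with survey-year contrasts, measures
    band-limited ambient noise (10-minute Leq in species 1/3-octave
    bands), and estimates passive-sonar detection ranges from source
    levels and noise percentiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
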