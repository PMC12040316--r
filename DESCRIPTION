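Package: krillclock
Title: Circadian Analysis of Krill Swimming Activity from Stacked-Detector
    Beam-Break Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes raw beam-break event streams from vertically stacked
    infrared detector columns into per-individual swimming-activity time
    series (upward-movement extraction, 10-minute binning, 0-1
    normalization, centered moving-average smoothing, daily detrending),
    detects circadian rhythmicity with a variance-normalized Lomb-Scargle
    periodogram and Horne-Baliunas significance, corrects each rhythmic
    individual's free-running period onto a 24-hour experimental day, and
    computes group-mean and average-day activity profiles and daily
    amplitude statistics (Mann-Whitney and paired t tests). Ships a
    synthetic-data generator that simulates clock-driven, light-masked,
    amplitude-damping activity of Antarctic krill under triangular
    light-dark regimes and constant darkness, down to sensor-level
    beam-break events, so the whole pipeline is verifiable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
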