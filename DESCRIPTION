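Package: clickpam
Title: Detection, Description and Classification of Odontocete Echolocation Clicks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for passive acoustic monitoring of sympatric dolphin
    species from single-hydrophone recordings. Reads calibrated underwater WAV
    audio, band-pass filters it, detects impulsive echolocation clicks with a
    spectral energy detector (per-bin signal-to-noise criterion on Welch
    segment spectra), groups and qualifies click trains by click count and
    inter-click interval, extracts eight spectral and temporal click
    parameters (-10 dB duration; peak, centroid, lower -3 dB and lower -10 dB
    frequencies; -3 dB, -10 dB and RMS bandwidths), compares species with
    nonparametric tests, and classifies species with a repeated random-forest
    out-of-bag procedure. Includes a ground-truthed synthetic click-train and
    feature-table simulator so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    randomForest,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
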