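Package: thighsleep
Title: Sleep Estimation from Thigh-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates nocturnal sleep from raw thigh-worn tri-axial
    accelerometer recordings using a recursive per-second sleep index:
    movement raises the index, quiescence lets it decay with a tunable
    time constant, and a fixed threshold separates wake from sleep.
    Includes the full processing chain (resampling, 0.5-10 Hz band-pass,
    noise gating, per-second activity, bout cleaning, awakening
    back-shift, lying-posture restriction, 30-s epoching), derivation of
    per-night sleep variables (sleep interval, total sleep time, latency,
    WASO, efficiency, awakening index), epoch-by-epoch validation against
    polysomnography hypnograms (sensitivity, specificity, accuracy,
    Bland-Altman agreement), a grid-search optimiser for the index
    parameters, and a ground-truthed synthetic night simulator so every
    stage can be exercised without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
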