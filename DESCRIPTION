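Package: mobigng
Title: Mobile Brain/Body Imaging Analysis of Go/NoGo Behavior, Gait, and ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for mobile brain/body imaging (MoBI)
    experiments that combine a visual Go/NoGo response-inhibition task with
    treadmill walking and optic flow. Provides signal-detection scoring of
    behavior (d-prime with extreme-rate corrections), heel-marker gait event
    detection and stride-variability metrics (stride time, stride length,
    step width, and their CV%), stimulus-locked ERP extraction (zero-phase
    band-pass filtering, average reference, spherical-spline bad-channel
    interpolation, epoching with baseline correction, two-pass peak windows
    for P2/N2/P3, difference waves and topographic segment means), pointwise
    t-statistic cluster maps with a consecutive-sample run-length criterion,
    and mixed repeated-measures ANOVA with Greenhouse-Geisser correction and
    partial eta squared. A deterministic synthetic-data generator emulates
    the behavioral, EEG, and motion-capture streams of such a study so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
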