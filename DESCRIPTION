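Package: arcpulse
Title: Pulse Analysis of Arcuate Kisspeptin Neuron Calcium Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of synchronous calcium episodes
    (SEs) of arcuate kisspeptin neurons recorded by fiber photometry across
    the estrous cycle and reproductive aging. Provides delta-F/F
    normalization with global and peri-event baselines, per-animal
    calibrated pulse detection with a full-width-at-half-maximum gate and a
    40 percent height threshold, quarter-maximum waveform metrics,
    estrous-cycle staging from vaginal cytology with cycle counting and
    senescence classification, alignment of recordings to proestrus by the
    dark/light suppression ratio, cohort-level summaries and statistical
    test dispatch, relative qPCR quantification by the 2^-ddCt method, and a
    synthetic-data generator that emulates the statistical structure of
    6-hour photometry sessions so the whole pipeline is testable without
    raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    multcomp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
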