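Package: svflux
Title: Quantification of Synaptic Vesicle Exo/Endocytosis from pHluorin Imaging
Version: 0.1.0
Authors@R: person("svflux", "maintainers", email = "maintainers@svflux.dev", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for quantifying synaptic vesicle
    cycling from pHluorin reporter (e.g. VGLUT-pHluorin) time-lapse movies of
    C. elegans sensory neurons: x-y drift registration, rolling-ball background
    subtraction, automated axon segmentation with flanking background ROIs,
    background-fluctuation and photobleach correction, deltaF/F normalization,
    constrained multi-exponential decay fitting with AICc model selection, time
    derivative and peak-response summaries, and trial-level aggregation. Includes
    a synthetic-data generator built on a two-pool kinetic model of tonic
    (AWC-like) and phasic (ASH-like) exo/endocytosis with calcium-coupled
    release and activity-dependent retrieval acceleration, rendered into
    realistic noisy movies so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
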