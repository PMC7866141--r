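Package: ThermoTrack
Title: Two-Plate Thermal Place Preference Tracking and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-plate thermal place preference assay in mice.
    Provides a frame-differencing video tracker that assigns a freely moving
    animal to the left or right thermal zone, quantification of percent time
    per zone across a nine-session 0-45 degree Celsius protocol, repeated
    measures ANOVA with Tukey multiple comparisons of zone occupancy across
    timepoints, and a classifier that declares an analgesic effect as loss or
    reversal of thermal preference. A stochastic thermotaxis simulator and
    grayscale video renderer generate fully synthetic sessions with ground
    truth, so every stage of the pipeline can be validated without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    EBImage,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'ThermoTrack-package.R'
    'protocol.R'
    'simulate-agent.R'
    'simulate-trajectory.R'
    'cohort.R'
    'render.R'
    'track.R'
    'benchmark.R'
    'stats.R'
    'cli.R'
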