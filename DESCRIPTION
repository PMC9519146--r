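Package: timedecode
Title: Population Decoding of Elapsed Time from Spike Trains During Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how elapsed-time encoding evolves across
    brain regions while animals learn a self-timed response-duration task.
    Provides a data model for behavioural trial tables and sorted spike
    trains, a double-Gaussian mixture fit for bimodal hold-duration
    distributions, peri-event epoching and Gaussian-kernel rate estimation,
    a shrinkage-regularised linear discriminant time-bin decoder with
    trial-grouped cross-validation, climbing (ramping) activity detection,
    jackknife leave-one-animal-out inference, and an inhomogeneous-Poisson
    synthetic-data generator so that every stage of the pipeline can be
    exercised end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'constructors.R'
    'behavior.R'
    'stats.R'
    'lda.R'
    'decoding.R'
    'methods.R'
    'spiking.R'
    'session-io.R'
    'pipeline.R'
    'synthetic.R'
    'timedecode-package.R'
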