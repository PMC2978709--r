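Package: nmjquant
Title: Quantal and Morphometric Analysis of Neuromuscular and Spinal Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantal analysis of neuromuscular transmission and count-based
    morphometry for mouse models of motor-circuit disease. Implements event
    detection and amplitude conditioning for intracellular endplate recordings
    (nonlinear-summation correction, normalization to -50 mV), direct-method
    quantal content, paired-pulse facilitation, Elmqvist-Quastel estimation of
    the readily releasable pool with release probability, muscle twitch and
    tetanic force analysis (indirect/direct stimulation ratio, specific force),
    and group statistics for per-neuron synapse counts, innervation
    classification, stereological totals and microglia association. A
    synthetic-data module simulates every input class (Poisson-timed miniature
    endplate potentials, binomial evoked release from a depletable vesicle
    pool with facilitation and replenishment, force waveforms, over-dispersed
    count tables) so the whole pipeline is testable against known ground
    truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
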