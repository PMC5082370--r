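Package: dropclock
Title: Stochastic Circadian Oscillators and Cell-to-Cell Synchronization in
    Droplet-Encapsulated Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of stochastic circadian oscillators
    measured one cell at a time in microfluidic droplets.  Provides an exact
    Gillespie simulator for a transcription-translation negative-feedback
    clock network with bursting gene states, a mean-field quorum-sensing
    model and a Kuramoto phase model of within-droplet coupling, a synthetic
    experiment generator with a quadratic detector-noise model and a shared
    reference channel, trajectory preprocessing (reference normalization,
    24-hour moving-average detrending, quality control), per-cell
    periodograms and Hilbert phases, propagation of detector noise to the
    periodogram with a stochastic/experimental variance partition and a
    harmonic analysis of variance, Metropolis ensemble fitting of the clock
    model to average periodograms, and intraclass-correlation
    synchronization surfaces with resampling controls and companion
    synchrony measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
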