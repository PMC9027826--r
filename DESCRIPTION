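Package: cctcsim
Title: Neural-Mass Simulation and Closed-Loop fNIRS-Driven Stimulation of
    the Cortico-Cerebello-Thalamo-Cortical Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating noninvasive electrical stimulation of the
    cortico-cerebello-thalamo-cortical (CCTC) loop and for prototyping
    closed-loop, fNIRS-driven cerebellar stimulation. Provides a
    seven-population neural-mass model of the thalamocortical basal-ganglia
    circuit with deep-cerebellar-nuclei input, generators for tDCS, tACS and
    temporal-interference (two kHz-carrier) stimulation waveforms with
    analytic-signal envelope demodulation, Welch spectral analysis with
    oscillation-band classification and gamma-to-beta shift detection, a
    two-wavelength fNIRS processing chain (modified Beer-Lambert conversion,
    motion correction, infra-slow band-pass filtering, GLM with a Gaussian
    basis and short-separation regression), a phase-amplitude-coupled
    closed-loop 4 Hz stimulation controller driven by infra-slow
    oxyhemoglobin phase, and seeded synthetic-session generators so every
    analysis is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
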