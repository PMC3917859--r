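Package: pmjsim
Title: Purkinje-Myocyte Junction Coupling and Reentry Dynamics in Excitable Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational study of how the cardiac Purkinje system
    couples to working myocardium during reentrant arrhythmia. Grows fractal
    Purkinje networks on triangulated endocardial surrogate surfaces with a
    controllable density of Purkinje-myocyte junctions (PMJs), simulates the
    electrical interaction between a one-dimensional Purkinje cable network and
    a two-dimensional monodomain tissue sheet through an asymmetric resistive
    junction model, induces reentry with an S1-S2 cross-field protocol, and
    quantifies the dynamics with mean firing rate, phase-singularity and
    wavebreak-incidence measures, and bidirectional junctional conduction
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
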