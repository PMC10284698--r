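Package: sterolentropy
Title: Entropic Repulsion Analysis of Sterol Surface Layers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantifying entropic repulsion of
    bioadhesion by spin-coated sterol multilayers. Implements reaction-order
    kinetics of interfacial polarity adaptation with AICc model selection,
    quartz crystal microbalance Sauerbrey mass conversion, temperature-
    dependent Langmuir adsorption thermodynamics and extraction of the
    entropic adsorption barrier from dG(T) slopes, a geometric estimator of
    the orientational entropy penalty, a coarse-grained Metropolis rotor
    simulator of a sterol multilayer interface with orientational
    observables (tilt angles, lateral orientation correlation, interfacial
    roughness, reorientation events), Soumpasis FRAP recovery fitting for
    lateral diffusion, and aggregation of multi-assay bioadhesion indices.
    Every input class can be generated synthetically, so the full pipeline
    is reproducible without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
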