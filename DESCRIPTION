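Package: condex
Title: Exchange Dynamics of Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and measures the exchange of material between a
    biomolecular condensate and the surrounding dilute phase. Provides a
    two-phase radial diffusion solver with an interface-conductance
    boundary condition and the associated recovery-timescale
    decomposition, closed-form theory for the interface conductance
    (mean-field profile integral, sharp-interface limit, sticker
    availability, slab-decay inversion, size crossover), a coarse-grained
    Langevin simulator of sticker-spacer polymers, and trajectory
    analysis protocols (clustering, density profiles, diffusion
    coefficients, survival labeling, flux measurement, in-silico FRAP,
    bounce detection) for quantifying interface resistance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
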