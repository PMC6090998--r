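Package: fibroscape
Title: Length-Scale Effects of Simulated Fibrosis in 2D Human Atrial Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic simulation of electrical activation, recovery and
    re-entry in two-dimensional human atrial tissue with smoothly varying
    diffusion used to represent diffuse and focal fibrosis. Provides the
    Courtemanche-Ramirez-Nattel (CRN) human atrial cell model with normal and
    AF-remodelled parameter variants, Gaussian random field sampling by
    circulant embedding to build heterogeneous diffusion fields with
    inexcitable fibrotic regions, an explicit finite-difference monodomain
    solver with adaptive time stepping, S1S2 and decremental pacing protocols
    plus spiral-wave initiation by the phase-distribution method, and analysis
    of activation, recovery and action potential duration maps, conduction
    velocity, beat counts and sustained re-entry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
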