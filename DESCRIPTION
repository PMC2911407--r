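Package: e2afiber
Title: Chromatin Fiber Simulation with the Extended Two-Angle Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Monte Carlo simulation of 30 nm chromatin
    fibers using the extended two-angle nucleosome geometry with excluded
    volume and histone-depletion defects (linker-histone and nucleosome
    skips). Computes structural observables of simulated ensembles: the
    nucleosome pair distribution function in three dimensions and after
    planar projection, the radial pair distribution g(r) and isotropic
    scattering function S(q), per-genomic-separation distance statistics,
    persistence length and linear compaction estimates, and random-collision
    (loop) statistics with genomic interaction maps comparable to
    chromosome-conformation-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
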