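Package: nlmag
Title: Nonlinear Magnetophoresis of Superparamagnetic Beads on Micromagnet Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale simulator and analysis toolkit for nonlinear
    magnetophoresis (NLM) on microfabricated magnet arrays. Computes
    magnetostatic flux-density landscapes of micromagnet lattices under a
    rotating external field by dipole rasterization (validated against the
    analytic field of a uniformly magnetized rectangular prism), transports
    superparamagnetic bead monomers and rigid dimers with overdamped dynamics,
    estimates critical and immobilization frequencies from closed-form and
    simulated velocity-frequency profiles, simulates the frequency-selective
    monomer/dimer separation protocol, and provides counting statistics for
    magnetic-bead-assembly (MBA) aggregation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
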