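Package: cyclopep
Title: Computational Scaffolding for Macrocyclic Peptide Binder Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational side of head-to-tail macrocyclic
    peptide binder design: cyclic relative positional encodings for
    macrocycle chains and macrocycle-target complexes, backbone
    construction from torsions with ideal geometry and cyclic-coordinate-
    descent ring closure, ring-closure validation, cyclic-aware
    phi/psi statistics, Kabsch superposition and the two C-alpha r.m.s.d.
    conventions used for design-versus-crystal comparison, TM-score with
    cyclic register search and greedy threshold clustering, numerical
    solvent-accessible surface area with spatial aggregation propensity
    and buried-interface-area metrics, hotspot contact coverage, and the
    multi-stage design-selection funnel with named campaign presets.
    Includes seeded synthetic generators for closed macrocycle backbones
    and metric tables with planted pass/fail structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
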