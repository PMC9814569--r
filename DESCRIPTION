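Package: dmdpep
Title: Discontinuous Molecular Dynamics of Charge-Complementary Peptide
    Co-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained, event-driven (discontinuous) molecular dynamics
    for beta-sheet fibrillizing peptides, using a four-bead-per-residue chain
    model with hard-sphere cores, square-well sidechain interactions and a
    directional backbone hydrogen-bond well, integrated exactly between
    events under an Andersen thermostat.  Includes sequence-level charge
    analytics for charge-complementary peptide design (net charge, Coulombic
    attraction ratios, self-association heuristics), assembly-kinetics
    analysis of trajectories (hydrogen-bond counts, free/oligomer/fibril
    cluster classification, strand-order statistics within beta-sheets),
    small biophysical calculations (mean residue ellipticity, secondary
    chemical shifts), and scenario generators that build every input the
    pipeline needs, from idealized beta-sheet fixtures to scaled-down
    co-assembly simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
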