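Package: helixcm
Title: Conformational Memories Sampling and Kink Geometry for Transmembrane Helices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring and quantifying the shape of G-protein-coupled
    receptor (GPCR) transmembrane helices. Implements the two-phase Monte
    Carlo/simulated-annealing "Conformational Memories" sampler over hinge-region
    backbone dihedrals, helix-axis fitting and kink geometry (bend, wobble and
    face-shift angles about a hinge residue), Ballesteros-Weinstein residue
    numbering, classification of GPCR microswitches (chi1 rotamer states, the
    ionic lock, toggle-switch triads, sodium-pocket and inter-helical contact
    audits, aromatic-stacking classes), systematic torsion scans with
    conformational-cost accounting, and per-residue decomposition of
    ligand-receptor Coulombic and van der Waals interaction energies. Includes
    seed-deterministic synthetic-structure generators (ideal and kinked
    alpha-helices, side-chain rotamer probes, toy ligand-pocket complexes) with
    machine-readable ground truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    bio3d,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
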