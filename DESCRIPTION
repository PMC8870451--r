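Package: ionpocket
Title: Sodium-Pocket Analysis for Receptor Simulations: Coordination
    Shells, Continuum Electrostatics and Sequence Phylogenetics
Version: 0.1.0
Authors@R:
    person("Ionpocket", "Developers", email = "ionpocket@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the allosteric sodium binding site of
    class A G-protein-coupled receptors and similar ion pockets. Provides
    ion coordination-shell assignment, ligand occupancy and coordination
    statistics, ion RMSD, chi1 rotamer classification and hydrogen-bond
    occupancy from molecular-dynamics trajectories; dual-boost accelerated
    MD parameterization; a finite-difference linear Poisson-Boltzmann
    solver with a smooth Gaussian dielectric for grid-energy binding free
    energies and single-site pKa shifts; a sequence pipeline with pairwise
    identity, greedy identity clustering, neighbor-joining trees with
    bootstrap supports and Ballesteros-Weinstein position annotation; and
    seeded synthetic generators (trajectories, energy series, charge
    systems, sequence families) with exact ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
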