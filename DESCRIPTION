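Package: confevo
Type: Package
Title: Multi-Objective Evolutionary Conformational Sampling for Small
    Molecules
Version: 0.1.0
Authors@R: person("Confevo", "Developers", role = c("aut", "cre"),
    email = "confevo.dev@example.org")
Description: Torsion-space conformer generation for drug-like small molecules
    driven by an epsilon-dominance multi-objective evolutionary algorithm.
    Two sampling modes are provided: a pure force-field mode whose objectives
    are van der Waals and torsion-strain energies, and a multiple-empirical-
    criteria mode that adds geometric dissimilarity to the input conformation
    and the radius of gyration as diversity objectives. The package includes
    Tripos mol2 input/output, two interchangeable empirical force-field
    backends with bounded conjugate-gradient refinement, symmetry-aware
    best-fit RMSD, benchmark analytics (cumulative recovery tables, ensemble
    statistics, scaled energy/gyration heat maps), a synthetic molecule
    generator with planted target conformations, and a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
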