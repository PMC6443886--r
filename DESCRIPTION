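Package: triazolamer
Title: NMR-Restrained Conformational Analysis of Peptidotriazolamer Foldamers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the conformational analysis of 1,4-disubstituted
    1H-1,2,3-triazole peptidotriazolamers: parsing of foldamer sequence
    notation into a coarse-grained topology, internal-coordinate structure
    building with triazole-aware backbone torsions, conversion of ROESY
    cross-peak intensities into upper-bound interproton distance restraints,
    restrained simulated-annealing conformational search in torsion space with
    iterative restraint pruning, and trajectory analytics (superposition RMSD,
    radius of gyration, phi/psi distributions, hierarchical RMSD clustering
    with representative selection, and radial distribution functions).
    Includes a synthetic-data generator providing template conformers,
    two-state trajectory mixtures and forward-modelled ROESY peak tables with
    known ground truth, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
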