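Package: presstraj
Title: Pressure-Perturbation Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how hydrostatic pressure perturbs protein
    conformational ensembles, built around monomeric actin as the model
    system. Provides estimators for excluded volume, solvent-accessible
    surface area and isothermal compressibility from volume fluctuations; a
    thermodynamic-cycle free-energy decomposition combining conformational
    energy, continuum (Poisson) polar solvation, surface-tension nonpolar
    solvation and quasi-harmonic solute entropy; geometric detection and
    classification of salt bridges and hydrogen bonds by secondary structure
    and subdomain; active-site geometry statistics for the ATP/Mg(2+) pocket
    including nucleophilic-water assignment and binned free-energy surfaces;
    and synthetic-ensemble generators with analytic ground truth for
    validating every estimator.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
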