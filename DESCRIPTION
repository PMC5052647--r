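Package: btpcorr
Title: Linear and Nonlinear Correlation Analysis of Protein Backbone Torsional Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Screens pairs of protein backbone dihedral angles (phi/psi) for
    linear and nonlinear dynamical correlations. Computes circular
    (Fisher-Lee) correlation coefficients and histogram-based mutual
    information for every backbone torsional pair, separates linear from
    nonlinear pairs with a calibrated maximum-possible-mutual-information
    contour, counts torsional-state peaks in marginal and joint angle
    distributions, and provides convergence, permutation-null and
    trajectory-subset diagnostics. Includes a von Mises Markov-switching
    simulator of torsion trajectories with known ground truth for validating
    the whole pipeline, plus pseudo-geometry so distance- and
    secondary-structure-stratified analyses can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    withr,
    jsonlite,
    bio3d,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
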