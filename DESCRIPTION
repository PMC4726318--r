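Package: memrate
Title: Membrane Receptor Oligomerisation Kinetics and Lipid Environment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of receptor oligomerisation kinetics in
    model membranes. Provides a seeded two-dimensional Brownian-dynamics
    generator of membrane trajectories with known ground truth, periodic
    trajectory containers and readers, centre-of-mass contact detection and
    oligomer clustering, lipid radial distribution functions and solvation
    shell reports, saturated/unsaturated demixing metrics, translational and
    rotational diffusion estimation from mean squared displacements and
    orientation autocorrelation, phospholipid-to-fatty-acyl-tail composition
    accounting, and BRET saturation-curve analysis with hyperbolic versus
    bystander model selection and paired condition comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
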