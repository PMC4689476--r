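Package: smacsim
Title: Elastohydrodynamic Simulation of Immunological-Synapse Protein Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the passive formation of supramolecular activation
    cluster (SMAC) patterns in the immunological synapse. Couples thin-film
    lubrication drainage of the synaptic cleft, membrane bending and protein
    spring mechanics, and height-gated binding kinetics of two receptor-ligand
    species (TCR-pMHC and LFA-ICAM) into a sixth-order nonlinear PDE system
    integrated with a semi-implicit scheme on periodic-square or disk domains.
    Provides the dimensionless groups and scaling laws for cluster size and
    drainage times, pattern metrics (bound-receptor totals, micro-cluster
    segmentation, bulls-eye detection), and (tau, B) phase-diagram sweeps,
    with tidy tabular outputs and ggplot2 visualisation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    igraph,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
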