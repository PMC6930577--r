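Package: mdoc
Title: Molecular Dynamics with Orientational Constraints for NMR-Driven
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restrained molecular dynamics for small flexible molecules in
    which time-averaged residual dipolar coupling (RDC) tensors, NOE
    distances and vicinal 3J couplings act as pseudo-forces (MDOC:
    molecular dynamics with orientational constraints). All nine components
    of each dipolar tensor are constrained through an exponential-memory
    running average, so no alignment (Saupe) tensor has to be assumed
    during the simulation. The package also provides the alignment-based
    comparison machinery (SVD Saupe fitting for single structures and
    population-weighted conformer ensembles), the n/chi-squared, outlier
    and fidelity quality criteria, Q factors, rotamer population analysis,
    complex dihedral principal component analysis, and a synthetic-data
    generator that builds toy rotor molecules and noisy pseudo-experimental
    constraint tables from reference ensembles with known rotamer
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d,
    withr
Config/testthat/edition: 3
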