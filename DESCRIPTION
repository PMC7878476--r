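Package: xlinkr
Title: Integrative Cross-Linking Mass Spectrometry Restraint Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of integrative cross-linking
    mass spectrometry (XL-MS) studies of chaperones and other multidomain
    proteins: exact monoisotopic mass accounting for cross-linker chemistries
    (ADH, DMTMM, DSS), cross-link table handling with domain classification
    and contact maps, distance-satisfaction scoring of structural ensembles,
    restraint-driven coarse-grained chain collapse, hydrodynamic size
    estimation (radius of gyration, Kirkwood approximation, Marsh-Forman-Kay
    chain-length relation), sequence charge profiling (NCPR), NMR chemical
    shift perturbation analysis of HSQC titrations, and equilibrium models
    with ligand depletion for fluorescence polarization binding and
    competition assays. Includes seeded synthetic-data generators so every
    stage can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    minpack.lm,
    bio3d,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
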