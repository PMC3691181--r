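Package: venomcomp
Title: Phylogenetic Comparative Analysis of Snake Venom Proteome Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for phylogeny-based comparative analysis of compositional
    venom-proteome data: construction of Brownian-motion variance-covariance
    matrices from time-calibrated trees, arcsine-square-root preparation of
    protein-family relative abundances, covariance-matrix principal
    components with correlation-scaled loadings, Blomberg's K with a
    tip-randomization permutation test, phylogenetic generalized least
    squares regression of venom traits on diet, and Benjamini-Yekutieli
    false-discovery-rate control. Includes simulators for pure-birth trees
    and Brownian traits with tunable phylogenetic signal, and a packaged
    Sistrurus rattlesnake venom/diet dataset with an end-to-end analysis
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
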