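Package: gapscape
Title: Conservation Gap Analysis with Effort-Corrected Endemism and
    Phylogenetic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for protected-area gap analysis on planar landscapes:
    hexagonal gridding of occurrence records, sampling-effort surfaces and
    effort-corrected weighted endemism, Faith phylogenetic diversity and
    phylogenetic weighted endemism on supertrees assembled by matrix
    representation with parsimony (parsimony ratchet search), simple
    species distribution models (Bioclim, Domain, Mahalanobis, GLM) with
    minimum-training-presence thresholds and pseudo-absence AUC screening,
    and protection accounting by protected-area category, biome and
    designation epoch. A synthetic-landscape generator with known ground
    truth supports parameter-recovery testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
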