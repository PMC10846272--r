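Package: betanull
Title: Null-Model Inference of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic and taxonomic null models for partitioning pairwise
    community turnover into ecological assembly processes. Implements
    abundance-weighted beta mean nearest taxon distance (betaMNTD), its
    standardized form betaNTI under a tip-shuffle null, the abundance-informed
    Raup-Crick metric on Bray-Curtis dissimilarities (RC-BC), and the
    five-process classification (heterogeneous and homogeneous selection,
    dispersal limitation, homogenizing dispersal, drift) of Stegen et al.
    (2013) <doi:10.1038/ismej.2013.93>. Ships the supporting community-ecology
    toolkit used alongside these models: rarefaction and Good's coverage,
    Bray-Curtis dissimilarity, NMDS, ANOSIM, SIMPER, VIF-pruned canonical
    correspondence analysis, medoid water-mass clustering, spheroidal
    geographic distances, distance-decay, PCNM spatial eigenvectors, Mantel
    and partial Mantel tests, and three-block variation partitioning with
    adjusted R-squared. A synthetic-community simulator assembles OTU tables
    under each of the five processes so the whole inference chain can be
    validated by process recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    biomformat,
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
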