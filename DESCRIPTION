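Package: kuromix
Title: Water-Mass Mixing and Microzooplankton Community Assembly Along a
    Boundary-Current Intrusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how a western-boundary-current intrusion
    structures a marine microbial eukaryote (ciliate) community. Estimates
    the intruding water-mass fraction per sample from CTD hydrography with a
    two-end-member isopycnal mixing model, classifies stations into more and
    less influenced provinces, and analyses an OTU table against that
    gradient: rarefaction and beta-diversity (Bray-Curtis, PCoA, UPGMA,
    ANOSIM), phylogenetic and compositional null models (betaNTI and
    abundance-based Raup-Crick) with ecological process fractions,
    current-sensitive OTU identification by intersecting a permutation
    indicator statistic with a negative-binomial likelihood-ratio test,
    Spearman co-occurrence networks with modularity analysis, and
    distance-matrix statistics (Mantel, partial Mantel, multiple regression
    on distance matrices). Includes a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    edgeR,
    mclust,
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
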