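Package: mycorrnet
Title: Structure of Below-Ground Plant-Fungus Association Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Community-scale analysis of root-associated fungal metabarcoding
    data across multiple forest sites. Provides quality filtering and
    rarefaction of sample-by-OTU read-count tables, aggregation into
    plant-by-fungus association matrices, extraction of mycorrhizal
    guild-specific partial networks, bipartite structural indices
    (connectance, H2' network-level interaction specificity, weighted NODF
    nestedness, checkerboard C-score), sample-level host-label-shuffle null
    models with standardized relative (z-score) indices, cross-site
    comparison by ANOVA and correlation-matrix PCA, and a synthetic data
    generator that emulates multi-forest root-sampling designs with tunable
    host specificity, guild structure, and nestedness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vegan,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
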