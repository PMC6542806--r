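Package: domitax
Title: Dominant Soil Fungal Phylotypes: Dominance Classification,
    Co-Occurrence Clusters, Environmental Drivers and Genomic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies globally dominant phylotypes in a phylotype-by-sample
    amplicon survey using three criteria (top-decile total read share,
    within-biome frequency, habitat breadth across biomes), groups the
    dominant set into ecological clusters from a thresholded positive
    Spearman co-occurrence network with Louvain modularity, quantifies the
    clusters' environmental drivers via semi-partial Spearman correlations
    with an optional latitude/longitude spatial control, predicts cluster
    abundance over environmental grids with cross-validated evaluation, and
    compares genome-size-standardised gene-class frequencies between
    dominant and non-dominant genome sets with permutation tests. Includes a
    Dirichlet-multinomial community simulator with planted ground truth
    (dominant generalists, niche-structured specialists on an aridity
    gradient, trait-enriched genome groups) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    ranger,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
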