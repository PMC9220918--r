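Package: rarephylo
Title: Rarefaction, Core Partitioning and Phylogenetic Null Models for
    Amplicon Community Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for the diversity analysis of amplicon
    sequence variant (ASV) community tables along a spatial transect:
    seeded rarefaction, Shannon alpha diversity, Bray-Curtis and Jaccard
    beta diversity with UPGMA clustering, Mantel tests against geographic
    distance, shared-core ASV intersection counts, rare/abundant
    subcommunity partitioning by per-site quartiles or whole-table
    relative abundance, Faith's Phylogenetic Diversity, Phylogenetic
    Species Clustering (PSC), and a richness-preserving randomization
    null model yielding standardized effect sizes classified as
    clustered, null, or overdispersed. Includes a synthetic community
    generator that emulates a hypersaline microbial mat's structure (a
    tiny dominant shared core plus a long rare tail, with tunable
    phylogenetic clustering of the core) so the whole pipeline runs with
    no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils,
    vegan,
    withr
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
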