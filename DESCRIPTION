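Package: aquastab
Title: Neutral Assembly and Stability Analysis of Aquaculture Water Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for 16S ZOTU count tables from a microalgae-
    amended shrimp-rearing-water experiment (4 treatment groups x 3 replicates
    x 8 time points x 2 bacterial lifestyles). Implements Sloan's neutral
    community model with beta-approximation immigration fitting, 95%
    prediction-interval partitioning of taxa and family-level partition
    summaries; the average variation degree (AVD) community-stability index;
    and the supporting distance-based multivariate statistics (Bray-Curtis,
    PCoA, RDA, db-RDA, PERMANOVA with interactions, ANOSIM, MRPP, Spearman
    Mantel, UPGMA clustering). A synthetic-data generator emulating the study
    design makes every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
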