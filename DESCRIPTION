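Package: phyloRI
Title: Phylogenetically Weighted Resistance of Forest Communities Along
    Invader Expansion Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stratified vegetation surveys along an
    invader expansion gradient. Computes species importance values from
    plot records, taxonomic alpha-diversity (Margalef, Gini-Simpson,
    Shannon-Wiener, Pielou), Faith's phylogenetic diversity and the
    net relatedness and nearest taxon indices (NRI/NTI) under a
    taxa-labels null model, robust Theil-Sen and Mann-Kendall gradient
    trend statistics with Kruskal-Wallis and Dunn post hoc group tests,
    a phylogenetically weighted species Resistance Index, and redundancy
    analysis with variance partitioning of diversity onto invader cover
    and soil drivers. Includes a synthetic-gradient generator that
    emulates a four-stage bamboo-expansion chronosequence with known
    ground truth, so every stage of the pipeline is testable end to end.
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
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    igraph,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
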