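Package: reopairs
Title: Differentially Ranked Gene Pairs and Pathway Enrichment from
    Within-Sample Expression Orderings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rank-based case/control comparison of gene expression that is
    insensitive to batch effects and between-sample normalization. Within
    each sample only the relative ordering of every gene pair is used;
    pairs whose ordering frequencies differ between phenotypes
    (differentially ranked, DR, gene pairs) are found with a batched
    Fisher exact test and Benjamini-Hochberg correction, cross-dataset
    reproducibility of DR pairs is quantified with an exact binomial
    concordance test, and pathways enriched with DR pairs are detected by
    a cumulative hypergeometric test over gene pairs. Because only
    within-sample orderings enter the analysis, case and control samples
    may come from different experiments, enabling pathway analysis of
    one-phenotype (e.g. tumor-only) datasets. Includes a synthetic-data
    generator with planted rank reversals, a full pipeline with
    provenance-stamped outputs, a label-permutation null harness, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
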