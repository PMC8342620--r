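Package: eqtl3d
Title: Spatial eQTL Mapping from Hi-C Restriction-Fragment Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps trait-associated variants to the genes they regulate by
    combining restriction-fragment level Hi-C contact data with
    covariate-adjusted eQTL association testing. Provides in-silico
    restriction digestion, fragment-level contact indexing, SNP-gene
    spatial pairing, genotype and expression quality control (HWE exact
    test, TMM, inverse normal transform), linear-model eQTL mapping with
    Benjamini-Hochberg FDR, chromatin-state permutation enrichment,
    bootstrap overlap statistics, tissue-specific protein-protein
    interaction networks with Louvain modules and hypergeometric
    pathway over-representation, and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
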