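Package: mitocurate
Title: Phylogeny-Guided Curation of Mitochondrial Reference Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-automated curation of mitochondrial reference sequence
    databases for eDNA metabarcoding. Filters and subsamples GenBank
    mitogenome records, extracts and concatenates marker genes with
    synonym-tolerant matching, partitions records into order-level groups
    for scalable tree inference, detects taxonomy-versus-topology
    anomalies on rooted phylogenies (singleton, pairwise and cluster
    categories), ingests manual review decisions, and assembles a
    versioned, annotated reference database in which phylogenetically
    indistinguishable records carry explicit similar_to= ambiguity flags.
    Includes a synthetic-data module that generates GenBank records and
    trees with planted anomalies so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
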