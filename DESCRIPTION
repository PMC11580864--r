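Package: gutsplit
Title: Detection of Full-Length and Split Homologs of Human Proteins in Gut
    Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gut microbial homologs of human proteins from local
    alignment tables and genome feature annotations. Beyond conventional
    one-to-one ("full-length") homologs, the pipeline identifies "split"
    homologs: cases where a human protein is matched jointly, but not
    individually, by two or more neighboring same-strand genes on one
    microbial contig, the bacterial analog of a eukaryotic gene fusion.
    Downstream statistics include Gene Ontology term enrichment with
    Benjamini-Hochberg correction, subcellular localization odds ratios,
    classification of xenobiotic enzyme families from protein family
    descriptions, Faith's phylogenetic diversity summaries over a species
    tree, and filtering of pharmacogenomic reaction tables to drug-relevant
    enzymes. A seeded synthetic-data generator with planted ground truth and
    labeled decoy configurations supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    dplyr,
    GenomicRanges,
    rtracklayer,
    phangorn,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
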