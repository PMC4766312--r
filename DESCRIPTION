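Package: brinemag
Title: Downstream Analysis of Hypersaline Metagenomes: Community
    Profiles, Genome Bins, ANI, Read Recruitment and Proteome pI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for the downstream stages of a shotgun
    metagenome study of hypersaline, alkaline brines: classification of
    16S rRNA-containing reads into top-level taxon profiles, best-hit
    majority-vote binning of contigs with quality-control retention
    rules, fragment-based average nucleotide identity (ANI) and
    conserved-DNA fraction between genomes, marker-gene completeness
    bounds for draft genomes, read-recruitment abundance estimation in
    RPKG units, and isoelectric-point (pI) profiling of predicted
    proteomes to classify osmotic-adaptation strategies. A seeded
    synthetic-data generator emulates every input so the whole pipeline
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
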