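Package: pretrna
Title: Pre-tRNA Architecture and tRNA-Seq 3'-End Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of pre-tRNA gene architecture and small
    RNA-seq 3'-end classification. Builds transcript-oriented tRNA gene
    catalogs from genome FASTA plus BED12 or GtRNAdb-style annotations,
    scans downstream flanks for RNA polymerase III poly-T terminators to
    measure 3'-trailer lengths, summarises mature tRNA lengths, 5'-leader
    base composition (position frequency matrices, optionally split by the
    discriminator base N73) and leader/trailer Watson-Crick pairing
    avoidance, with one-way ANOVA and Tukey HSD cross-species comparisons.
    Classifies raw small-RNA reads by exact-match "fishing" against unique
    isoacceptor bait sequences, bins them by 3'-end (CCA-mature versus
    uridylate-tailed precursors U1-U10), normalises to counts per million,
    computes immunoprecipitation/input fold enrichment, cumulative tail
    tables, tail-presence scoring and copy-number correlations. Annotates
    protein multiple sequence alignments against a reference row using
    five side-chain conservation groups. A seeded synthetic-data generator
    produces genomes, annotations and read sets with exported ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stringi,
    jsonlite,
    yaml,
    withr,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
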