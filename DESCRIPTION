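Package: riderscout
Title: Structural Annotation and Comparative Genomics of LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: De novo structural detection of full-length LTR
    retrotransposons (long terminal repeat pairs, target site
    duplications, primer binding sites, terminal TG...CA motifs),
    greedy centroid family clustering, insertion dating from LTR
    divergence under a molecular clock, neighbour-joining phylogenies
    with Tamura-Nei distances, cis-regulatory-element enrichment
    against promoter and strand-matched random backgrounds with
    Fisher's exact test, filtering and summarising of cross-genome
    BLAST tabular homolog screens, per-locus DNA methylation and small
    RNA summaries, in-silico PCR copy coverage, and a synthetic-genome
    simulator with truth tables that makes the whole pipeline testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    BiocGenerics,
    ape,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
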