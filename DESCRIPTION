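Package: pipscan
Title: Genome-Wide Binding Site Discovery for Alkylating
    Pyrrole-Imidazole Polyamides from Pulldown Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies and statistically validates genome-wide binding
    sites of DNA minor-groove-binding pyrrole-imidazole polyamides from
    biotin-pulldown enrichment sequencing. Candidate regions are called by
    sliding-window chi-square comparison of pulldown versus input fragment
    counts across a sweep of window sizes, filtered by degenerate (IUPAC)
    motif matching on variant-reconstructed sequence, and validated by
    two-sample Kolmogorov-Smirnov comparison of unity-normalized
    differential coverage against sampled null motif positions with
    Benjamini-Hochberg correction and a 99.9th-percentile decision rule.
    Downstream utilities annotate sites to transcripts and promoters,
    profile chromatin context (DNase hypersensitivity, consensus
    heterochromatin, H3K27Ac proximity), integrate expression fold
    changes, screen pathways by a three-criteria test, audit scrambled
    motifs, and compare 9-mer composition. A seeded synthetic-data module
    generates genomes with implanted motif sites, enriched fragment sets
    and expression tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
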