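Package: alienscreen
Title: Multi-Evidence Screening for Prokaryote-to-Metazoan Horizontal Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate horizontally transferred genes of prokaryotic
    origin in a metazoan genome assembly by combining four independent lines
    of evidence: an Alien Index computed from protein homology-search
    e-values, consensus-taxonomy assignment of top protein hits, externally
    supplied gene-family flags, and a windowed nucleotide bit-score screen
    of the assembly against prokaryotic and eukaryotic databases. Candidate
    sets are cleaned with compositional (GC at codon positions 1 and 3),
    assembly-context (contig length, flanking genes) and expression filters
    that discriminate genuine transfers from co-assembled symbiont
    contamination, then classified by the number of supporting methods and
    of host-like features (GC band, codon-usage cluster from correspondence
    analysis, multiple exons, homologs in related sponge transcriptomes).
    Functional over-representation of the candidate set is assessed with
    one-sided Fisher's exact tests and Benjamini-Hochberg correction. A
    seeded synthetic-genome generator with a truth table supports
    end-to-end recovery testing without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
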