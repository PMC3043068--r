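Package: screcon
Title: Hybrid Single-Cell and Metagenomic Genome Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recover a draft genome of a low-GC target organism from
    a mixture of single-cell multiple displacement amplification (MDA)
    sequencing datasets and a bulk enrichment metagenome. Implements GC-content
    read filtering with homology-based rescue of high-GC conserved regions,
    split-alignment detection of MDA chimeras, contig shredding into
    pseudo-reads for consensus assembly, rarefaction-based genome size
    estimation, reference-guided orientation and ordering of assembly elements,
    and downstream genome statistics (reciprocal best hits, average nucleotide
    identity with an identity floor for non-corresponding regions, per-position
    sequence novelty, nucleotide and oligomer skews, codon usage against a
    nucleotide-matched scrambled control, and quality-score based expected
    error budgets). A seeded synthetic-data generator emulates per-cell MDA
    amplification bias, chimeric reads, 454-like read lengths and qualities,
    and sample barcodes, so every stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
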