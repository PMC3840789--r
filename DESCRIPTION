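Package: ribostop
Title: Stop Codon Readthrough Analysis for Ribosome Profiling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting and quantifying stop
    codon readthrough in ribosome profiling (ribo-seq) experiments. Converts
    footprint and mRNA-fragment alignments into strand-aware fractional
    coverage using a P-site trimming rule, builds a countable coordinate
    space by merging exon-sharing loci and masking degenerate (multi-mapping)
    positions, enumerates candidate C-terminal protein extensions between an
    annotated stop codon and the next in-frame stop, scores them with
    density, coverage and ribosome-release filters, and tests for
    differential readthrough between samples with exact statistics.
    Companion diagnostics include metagene profiles, ribosome release
    scores, read-length distributions, triplet phasing tests, per-position
    mismatch scans that exclude genomic polymorphism and A-to-I editing
    artifacts, and a phase-specific Z-curve classifier of coding potential.
    A seeded synthetic-data generator emulates the statistical structure of
    ribosome profiling data (initiation/termination peaks, footprint length
    distributions, triplet phasing, configurable per-gene readthrough rates,
    3'-UTR contaminants, sequencing errors, polymorphisms and editing sites)
    so the whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    MASS,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
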