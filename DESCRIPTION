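Package: tribecall
Title: HyperTRIBE Editing-Site Calling and RBP Target Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Strand-aware A-to-G editing-site calling from stranded RNA-seq
    alignments for HyperTRIBE experiments in yeast. Calls editing sites under
    coverage/editing-percentage thresholds (e.g. r20e10), subtracts Hyper-only
    background editing, excludes single-nucleotide polymorphisms via a
    wild-type RNA sample, defines per-replicate and high-confidence target
    gene sets, computes replicate agreement, signal-to-noise and gene-set
    overlap statistics, and prepares edit-centred sequence windows with
    matched background for external motif discovery. Includes a synthetic
    stranded-library simulator with planted edits, SNPs, sequencing errors
    and PCR duplicates so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
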