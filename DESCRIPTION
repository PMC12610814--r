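Package: plastcub
Title: Codon Usage Bias Analysis for Plastid Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tidy analysis of synonymous codon usage bias in chloroplast
    (plastid) protein-coding genes. Reads coding sequences from FASTA or
    GenBank flat files, applies reproducible quality filters, and computes
    per-gene codon-usage statistics: positional nucleotide composition
    (GC1/GC2/GC3/GC12), relative synonymous codon usage (RSCU), synonymous
    codon usage order (SCUO), observed and expected effective number of
    codons (ENC) with the ENC-ratio classification, the codon adaptation
    index (CAI) and its complement used as an expression proxy. Provides
    parity-rule-2 (PR2) and neutrality-plot selection diagnostics,
    optimal-codon identification from high/low-expression gene libraries,
    RSCU-based hierarchical clustering of taxa with Newick export, and a
    seeded synthetic coding-sequence generator with known mutation- or
    selection-driven usage regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
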