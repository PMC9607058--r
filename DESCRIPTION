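Package: codonbias
Title: Codon Usage Bias and Host Adaptation Analysis for Viral Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for quantifying codon usage bias in complete viral
    coding sequences and scoring their adaptation to host codon usage.
    Implements nucleotide composition profiling, relative synonymous codon
    usage (RSCU), Wright's effective number of codons (ENC) with the
    expected-ENC curve for ENC plots, parity rule 2 (PR2) bias coordinates,
    the GC12-versus-GC3 neutrality regression partitioning mutation pressure
    from natural selection, principal component analysis of RSCU space, and
    the host-adaptation indices CAI, RCDI and SiD. Includes a synthetic
    coding-sequence generator with known mutation/selection/host-mimicry
    structure so every statistic can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
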