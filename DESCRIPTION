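Package: adipodyn
Title: Transcription-Factor Screen Hit Calling and Dynamic Binding Analysis for Adipogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting pro-adipogenic transcription factor function
    from arrayed overexpression screens and time-course genomic profiling.
    Implements plate-screen differentiation scoring with control-normalized
    z-scores and Bonferroni hit calling; genomic interval utilities with
    shifted-peak permutation nulls for co-binding and category enrichment;
    a negative-binomial differential count test with median-of-ratios
    normalization for dynamic-binding and expression classification;
    position-weight-matrix scanning at fractional score cutoffs with
    summit-centered motif density profiles; permutation tests for gene
    regulatory network targeting; and synthetic-data generators with planted
    ground truth for every analysis stage. All user-facing functions take and
    return tibbles and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
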