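Package: symbiomark
Title: Simultaneous Host-Barcode and Microbiome Amplicon Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for multi-target amplicon sequencing
    of insect hosts and their bacterial symbionts: primer-based binning of
    paired-end reads into marker bins (COI, 16S-V1V2, 16S-V4), read-pair
    merging and expected-error filtering, dereplication, UNOISE-style
    denoising into zero-radius OTUs, de novo two-parent chimera screening,
    greedy 97% identity clustering, best-hit taxonomy assignment,
    negative-control-based decontamination and abundance/depth filtering,
    host barcode selection with species verification, numt flagging,
    heteroplasmy calling and off-target (parasitoid, endosymbiont) detection,
    and population-level statistics (symbiont prevalence, rRNA-operon strain
    grouping, 16S region concordance, distance-based redundancy analysis with
    permutation tests, chi-square association). Includes a synthetic
    multi-marker run generator with ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
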