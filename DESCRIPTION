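Package: oligovote
Title: Alignment-Based Error Correction for DNA Data Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for studying multiple-sequence-alignment
    (MSA) based error correction in DNA data storage. Encodes arbitrary
    binary data into indexed oligonucleotides with the plain quaternary
    code (00-A, 01-T, 10-G, 11-C), corrupts reads through a uniform
    insertion-deletion-substitution (IDS) channel, aligns each cluster of
    noisy reads with MAFFT (FFT-NS-2) or a built-in center-star fallback
    aligner, calls a column-wise majority-vote consensus, and measures
    recovery as a function of error rate, sequencing depth and clustering
    accuracy. Includes experiment drivers for recovery-accuracy grids,
    minimum-depth curves, phase-transition scans and clustering-robustness
    studies, with tidy tabular results and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: MAFFT (optional; used when engine = "mafft")
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
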