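Package: polyeff
Title: Transcription and Translation Efficiency Analysis from Polysome
    Profiling Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two-fraction (polysomal versus non-polysomal),
    two-timepoint expression experiments such as early 3T3-L1 adipogenesis
    time courses. Computes per-gene transcription (TC) and translation (TL)
    efficiencies from log2 intensities, tests them with an empirical-Bayes
    moderated t-statistic and Benjamini-Hochberg adjustment, classifies genes
    into the nine TC x TL regulation groups, scans 5'UTR sequences for
    5' terminal oligopyrimidine (TOP) motifs, and tests group-wise motif and
    GO-term overrepresentation with Fisher's exact test. Includes a seeded
    synthetic-data generator with planted effects, TOP motifs and a toy GO
    DAG so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
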