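Package: gretarget
Title: Ranking Differentially Expressed Genes as Direct Transcription-Factor Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative prioritisation of differentially expressed genes as
    direct transcription-factor targets from ChIP-seq binding sites, open
    chromatin, enhancer-target annotation and binding-motif occurrences.
    Associates peaks to genes within a transcription-start-site window,
    computes distance-decayed regulatory potential with a cumulative-curve
    Kolmogorov-Smirnov activator/repressor test, scans position weight
    matrices with exact dynamic-programming p-values, combines per-gene
    annotation features by min-max scaling into a Normalized Annotation
    Score, and orders genes by the rank product of expression change and
    annotation score. Includes a seeded synthetic-data generator with known
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
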