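Package: replilicense
Title: Integrative Genomic Analysis of Replication Origin Licensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the integrative multi-omics
    analysis of replication origin licensing by a chromatin-organizing
    transcription factor. Implements peak colocalization with a
    random-region permutation null, knockdown-differential classification
    of binding and accessibility (including derivation of
    factor-dependent licensing peaks), RNase-controlled nascent-strand
    origin filtering with Fisher's exact test and Benjamini-Hochberg FDR,
    S1/S2/S3 origin-response classification, Repli-seq replication-timing
    assignment, A/B compartment-change classification from PC1
    eigenvectors with enrichment testing, an electron-microscopy
    nucleosome-occupancy statistic, and clone copy-number co-occurrence
    analysis against patient cohorts. A synthetic-data generator with a
    known truth ledger makes every stage testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
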