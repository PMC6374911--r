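Package: methdyn
Title: Differential Methylation Dynamics from Whole-Genome Bisulfite
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing methylome dynamics from whole-genome
    bisulfite sequencing count data: per-CpG differential methylation
    testing with Fisher's exact test and permutation-calibrated adaptive
    false discovery control, merging of differential sites into regions,
    genomic-compartment and cell-type enrichment statistics, anchored and
    gene-scaled methylation metaprofiles, co-methylation module discovery
    across methylome panels, and position-weight-matrix motif enrichment
    against flank-derived backgrounds. Includes a synthetic bisulfite
    data generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
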