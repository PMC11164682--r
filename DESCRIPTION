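Package: pbscreen
Title: Transposon Insertional Mutagenesis Screen Analysis with Gaussian
    Kernel Convolution Common Insertion Site Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for piggyBac (and similar DNA transposon)
    insertional mutagenesis screens: demultiplexing and trimming of
    splinkerette junction reads, conversion of alignments to per-lesion
    integration sites with PCR-duplicate merging, common insertion site
    (CIS) detection by Gaussian kernel convolution with per-chromosome
    permutation significance, gene-body annotation and candidate triage,
    and sum-of-z-score pathway signature scoring of expression cohorts.
    Includes a synthetic screen and expression-cohort generator with
    ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
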