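Package: np10
Title: Proteomic Evaluation of Genome Annotation Accuracy with the NP10 Metric
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark genome annotation accuracy from bottom-up
    proteomic identification results. Implements the NP10 statistic (the
    median molecular weight of the top decile of identified proteins ranked
    by peptides per protein), protein and peptide identification table
    input/output, sequence coverage and parsimony-based protein grouping,
    comparison of identification sets obtained from two annotation releases
    (peptide-overlap attribution by annotation change category and
    partial-protein improvement analysis), and a synthetic proteome and
    identification simulator with in-silico tryptic digestion so that the
    full pipeline can be exercised without mass spectrometry data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
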