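Package: loyscan
Title: Mosaic Loss-of-Y Quantification from Coverage and Amplicon Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies mosaic loss of the Y chromosome (LOY) in bulk
    sequencing data from male mammals. Implements a targeted-amplicon
    log10 dosage score, a whole-genome read-depth estimator that compares
    per-chromosome median window coverage against half the autosomal
    median, and windowed log2 coverage-ratio profiles over the Y
    male-specific region with median and variance summaries. Includes a
    negative-binomial synthetic-cohort generator with known loss
    fractions for benchmarking, a rank-based statistical battery with
    exact small-sample p-values and Benjamini-Hochberg correction, and
    screen-level orchestration with tidy outputs and ggplot2 figures.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
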