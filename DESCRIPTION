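Package: conntest
Title: Kernel Two-Sample Tests for Brain Connectivity Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group comparison of weighted brain connectivity graphs that share a
    fixed node correspondence. Implements the direct connection embedding and the
    associated characteristic Gaussian graph kernel, the kernel two-sample test
    (unbiased squared maximum mean discrepancy with a Monte-Carlo permutation
    null), a pooled empirical-CDF common representation space that makes
    structural and functional connectivity statistically comparable, and a
    differential statistic that tests whether one connectivity modality is more
    affected by a condition than another. Includes a leave-one-subject-out
    kernel SVM baseline with an exact binomial test, adjacency-matrix and manifest
    I/O, a synthetic two-class two-modality connectome generator for calibration
    and power analysis, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    kernlab,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
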