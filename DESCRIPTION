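Package: deconvmark
Title: Marker Gene Selection and Benchmarking for Cell-Type Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects cell-type marker genes from single-nucleus RNA-seq
    references using the Mean Ratio specificity statistic and classic
    one-vs-all contrasts, builds signature matrices, estimates cell-type
    proportions in bulk RNA-seq with a non-negative least-squares baseline
    (with optional cell-size adjustment), and benchmarks predictions against
    orthogonal imaging-derived cell compositions. Includes the sensitivity
    experiments used in deconvolution benchmarking (equal-proportion
    reference downsampling, donor subsampling, marker-set sweeps) and a
    synthetic-data generator that produces paired reference, bulk, and
    segmentation-table fixtures with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
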