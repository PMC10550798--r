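Package: cqpipe
Title: Post-Analytical Pipeline for RT-qPCR Microfluidic miRNA Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the post-analytical stages of RT-qPCR microfluidic
    (low-density array) miRNA profiling: quantification-cycle (Cq) calling
    under fixed, automatic and relative (efficiency-based) threshold
    algorithms; amplification-curve quality scoring and gating; call-rate and
    median-Cq filtering; reference-miRNA stability ranking by BestKeeper,
    geNorm, NormFinder and the comparative delta-Ct method with a
    geometric-mean comprehensive rank; geometric-mean normalization factors;
    and 2^-ddCq relative expression with Wilcoxon group tests,
    Kruskal-Wallis/Dunn threshold comparison and cross-method agreement
    statistics. Includes a seeded simulator for amplification curves and Cq
    data sets with known ground truth, so every stage is testable without
    instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
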