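Package: drugrank
Title: Signature-Similarity Ranking and Indication-Recovery Benchmarking for
    Shotgun Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks virtual-screening pipelines for multi-indication
    ("shotgun") drug repurposing. Given a drug-by-protein interaction score
    matrix from any docking or scoring method, computes per-compound
    proteome-signature similarity rankings by root-mean-square deviation,
    runs the leave-one-out indication-recovery benchmark (per-indication
    accuracy, pairwise accuracy and coverage at a grid of rank cutoffs),
    provides the analytic hypergeometric random control and its Monte Carlo
    twin, synthesizes per-indication decision-tree hybrids of multiple
    pipelines, and computes cross-pipeline divergence analytics (win/tie
    counts, net accuracy differences, Kolmogorov-Smirnov distribution
    comparison, drug-indication pair rank consensus, indication association
    networks). A synthetic-data generator with planted compound clusters and
    an i.i.d. null mode makes every analysis reproducible without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
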