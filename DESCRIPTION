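Package: retree
Title: Interactive Mixed Classification Trees with Relative-Expression Splits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Induction, interactive editing, and evaluation of binary
    classification trees whose internal nodes may carry univariate
    threshold tests, Top-Scoring-Pair (TSP) relational tests, or weighted
    TSP tests, all selected by the Gain Ratio criterion. Designed for
    transcriptomics-style samples-by-features tables where within-sample
    relative expression ordering carries class information. Provides
    deterministic greedy top-down induction with configurable stopping
    rules and no automatic post-pruning, manual editing operations (fold,
    unfold, update, rebuild, partial-test completion, top-split
    suggestions), train/test evaluation with confusion matrices and
    per-node instance assignments, a canonical JSON interchange format
    for trees, a synthetic data generator with planted rules, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    generics,
    ggplot2,
    withr,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
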