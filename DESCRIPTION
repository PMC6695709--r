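Package: dockfuse
Title: Consensus Scoring for Ensemble Docking by Rank-Based Data Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning per-structure docking scores from ensemble
    docking into consensus scores and for benchmarking the fusion rules that
    produce them. Implements seven data-fusion rules (minimum, maximum,
    arithmetic/geometric/harmonic means, median, Euclidean norm), the
    virtual-screening enrichment metrics AUC, average precision and BEDROC,
    and sum of ranking differences (SRD) with a minimax reference vector, a
    random-ranking null distribution and sevenfold cross-validation. Fusion
    rules are compared with one-way ANOVA and Tukey HSD post-hoc tests and
    summarised in four-dimensional bubble tables. A Gaussian synthetic-data
    generator produces docking-score matrices with realistic active/inactive
    imbalance, per-structure offsets and inter-structure correlation for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ggplot2,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
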