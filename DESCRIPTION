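Package: mirxtalk
Title: MicroRNA Regulators of Gene Pathway Cross-Talk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cross-talk between biological pathways from tumor
    versus normal expression data with a per-sample Discriminating Score,
    selects discriminative pathway pairs by Monte Carlo cross-validated
    random-forest AUC ranking, and identifies microRNA master regulators of
    the selected pairs via Kraskov k-nearest-neighbour mutual information
    regulons and a dual Fisher enrichment test. Includes a negative-binomial
    exact test for differential expression with a common qCML-style
    dispersion, Fisher pathway enrichment, a synthetic-data generator with
    planted ground truth for end-to-end validation, and tidy accessors plus
    ggplot2 autoplot methods for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
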