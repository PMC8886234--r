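Package: dysnet
Title: Dysregulated Gene Regulatory Network Analysis of Tumor Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dysregulated networks from paired normal/tumor expression
    profiles and a directed gene influence network. Per-edge regulation
    strengths (log expression ratios) are tested between groups with a
    moderated empirical-Bayes t-test or Welch's t-test; edges passing
    significance and effect-size thresholds form the dysregulated network,
    from which key genes are selected by a cumulative dysregulation-score
    rule. Downstream stages rank candidate driver genes by greedy covering of
    expression-outlier events through the influence network, score pathway
    and drug-target gene sets by hypergeometric enrichment, and compare
    survival between high- and low-expression groups with Kaplan-Meier
    curves and the log-rank test. A synthetic-data generator with planted
    ground truth supports end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
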