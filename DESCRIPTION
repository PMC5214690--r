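Package: thermoprofiler
Title: Downstream Community and Functional Analysis of Hot-Spring Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the downstream analysis of
    hot-spring (and other extreme-environment) metagenome surveys:
    lowest-common-ancestor taxonomic assignment from tabular alignment hits
    with rank-specific identity thresholds, gene / KEGG-ortholog / genome
    quantification with explicit paired-read counting rules, alpha and beta
    diversity (rarefaction, Shannon, Pielou, Hellinger, unweighted UniFrac,
    principal-coordinates analysis), exact rank-sum and Tukey group
    comparisons, per-ortholog odds ratios with pathway-level Fisher tests
    and reporter Z-scores, Spearman temperature-correlation screening with
    false-discovery-rate control, taxon-resolved pathway-completeness
    analysis, and a fully self-consistent synthetic-community generator
    with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    withr,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
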