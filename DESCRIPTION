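Package: sigshift
Title: Cell-Population Signature Genes and Directional Enrichment for
    Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for detecting shifts of cell-population-specific gene
    expression in bulk transcriptome comparisons, as used to read out
    immune-cell infiltration and tissue composition change in aging
    studies.  Provides moderated differential expression with
    empirical-Bayes variance shrinkage for two-group contrasts and
    genotype-by-age interactions, detection-based gene filtering,
    two-stage derivation of cell-population signature gene sets from a
    labeled reference compendium (fold-change then p-value then
    fold-change ranking), and a family of directional signature
    enrichment statistics: rank-sum fold-change bias with signed log10
    p-values, cumulative-overlap curves with Wilcoxon-Mann-Whitney AUC,
    and direction-count exact tests.  Includes qPCR relative-expression
    analysis with protected Fisher's LSD letter displays, and
    synthetic-data generators with known ground truth for end-to-end
    validation.
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
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
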