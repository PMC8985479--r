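Package: conjfdr
Title: Cross-Trait Conditional and Conjunctional FDR Analysis of GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering genetic loci shared between two complex
    traits from genome-wide association study (GWAS) summary statistics.
    Implements summary-statistic harmonization, linkage-disequilibrium (LD)
    aware genomic inflation control via iterated random pruning weights,
    conditional quantile-quantile enrichment curves, conditional and
    conjunctional false discovery rate (condFDR/conjFDR) estimation on a
    weighted empirical grid, LD clumping of significant variants into loci
    with gene annotation, and a from-scratch SKAT variance-component test
    for gene-level burden analysis of case-control genotype data. Ships a
    synthetic bivariate-GWAS generator (blockwise LD, trait-specific and
    shared causal variants, optional inflation) so the whole pipeline is
    testable without external data.
License: MIT
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
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
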