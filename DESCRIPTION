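Package: postgwas
Title: Post-GWAS Summary-Statistics Toolkit: QC, Fine-Mapping and Colocalisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the statistical stages that follow a genome-wide
    association scan: quality control and Bonferroni threshold ledgers for
    summary statistics, genomic-control inflation, linkage-disequilibrium
    reference panels with greedy pruning, locus definition and approximate
    conditional (joint) analysis reconstructed from summary data, Wakefield
    approximate-Bayes-factor fine-mapping with null-weighted posteriors and
    95% credible sets, and two-trait Bayesian colocalisation with a
    strong-colocalisation decision rule. A seed-deterministic synthetic GWAS
    generator (Gaussian-copula linkage disequilibrium, additive quantitative
    and liability-threshold binary traits) makes every stage testable at desk
    scale with known ground truth.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
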