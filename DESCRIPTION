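Package: homeobalance
Title: Expression Balance and Dosage Sensitivity of Homeologs After
    Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies relative expression differences (R_FPKM) between
    WGD-derived duplicate gene copies (homeologs) across tissues, relates
    expression balance to gene features under a dosage-balance framework,
    scores orthogroup dosage sensitivity from expected post-WGD copy
    numbers and a Dollo-parsimony propensity for gene loss, decomposes
    cis- and trans-regulatory divergence from allele-specific expression,
    and contrasts evolutionary fates of high- versus low-expression
    copies. Ships a synthetic-study generator in which a latent
    dosage-sensitivity parameter jointly drives expression balance, copy
    retention, sequence divergence, regulatory change, and premature-stop
    incidence, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
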