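Package: toxmodules
Title: Conserved Pathway Modules from Dose-Response Toxicogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pathway-centred pipeline for comparative toxicogenomics of
    dose-response expression experiments. Per-gene linear dose-time models
    rank genes by signed association significance for each chemical;
    preranked gene set enrichment (weighted running-sum statistic with a
    size-matched random-set null) turns ranked lists into pathway-by-chemical
    enrichment matrices; the iterative signature algorithm biclusters each
    matrix into transcriptional modules; and reciprocal best-hit matching
    with one-sided hypergeometric tests identifies modules conserved across
    experimental settings and species. Includes a synthetic-data generator
    emulating single-dose liver toxicogenomics designs (in vivo rat liver,
    primary rat and human hepatocytes) with planted pathway-chemical modules
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
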