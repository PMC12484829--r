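Package: allelicomp
Title: Allele-Resolved Gene Dosage Compensation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of gene dosage compensation from allele-resolved expression
    data in hybrid mouse pluripotent stem cells. Provides genotype sensing from
    allelic expression, identification of X-chromosome upregulation (XCU) genes
    against a half-of-biallelic null, copy-number-corrected region-wise
    compensation reports for X-linked and autosomal monosomic expression,
    integration with label-free proteomics, allele-resolved ChIP coverage
    quantification over promoters and gene bodies, and a synthetic-data
    generator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
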