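Package: hcpnorm
Title: Hidden Covariates with Prior Normalization for RNA-Seq Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes known and hidden confounding covariates from RNA-seq
    expression matrices through a unified residual framework. Implements
    ridge residualization on known technical covariates, principal-component
    (SVD) removal, an alternating known-plus-hidden scheme, and the HCP
    (Hidden Covariates with Prior) model, in which hidden factors carry a
    Gaussian prior centred on linear combinations of known covariates and
    are fitted by closed-form block coordinate descent. Includes
    construction of sequencing-depth, GC-bias and length-bias covariates,
    RPKM computation, a cis-eQTL evaluation (Spearman scan within a window
    of the transcription start site with Benjamini-Hochberg FDR), a
    co-expression evaluation (Pearson network, label propagation,
    cross-validated area under the precision-recall curve), and a seeded
    synthetic-data generator with planted truth for end-to-end testing.
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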