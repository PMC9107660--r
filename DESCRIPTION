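Package: crosstrait
Title: Cross-Trait Genetic Correlation, Pleiotropy and Mendelian
    Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking two complex traits with GWAS summary
    statistics alone: cross-trait LD score regression for heritability and
    genetic correlation with block-jackknife standard errors (overall and
    per chromosome); a quadratic-form gene-based SNP-set association test
    with genomic control; a composite-null intersect-union pleiotropy test
    over paired gene p-values with mixture-null calibration and FDR
    selection; a two-sample Mendelian randomization estimator suite (IVW,
    MR-Egger, weighted median, maximum likelihood, MR-PRESSO, multivariable
    IVW) with instrument clumping, fetal/maternal instrument
    classification, and an analytical power calculator; and a
    joint-significance mediation pipeline over an
    exposure-mediator-mediator-outcome causal chain. Includes synthetic
    summary-statistics generators with block LD so every stage is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
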