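Package: selblup
Title: Selection-Adjusted Genomic Prediction and Heritability Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (GBLUP) and restricted
    maximum likelihood (REML) heritability estimation with genomic
    relationship matrices whose per-SNP scaling encodes an assumed
    relationship between minor allele frequency and marker effect size
    (the selection exponent S). Supports the single-matrix GBLUP-S model
    and the five-component MAF-stratified GBLUP-SMS model, PLINK binary
    genotype input with quality control, quantitative-trait simulation
    under a chosen selection signature, cross-validated prediction
    accuracy, and a heritability-enrichment chi-square diagnostic for
    choosing S.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
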