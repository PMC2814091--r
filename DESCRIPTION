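Package: senemeth
Title: Differential DNA Methylation Analysis of Replicative Senescence and Donor Aging
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing Infinium-style beta-value methylation
    matrices from cultured mesenchymal stromal cells: beta computation from
    channel intensities, detection-p filtering and quantile normalization,
    per-CpG delta-beta contrast statistics with Student's t tests and
    Benjamini-Hochberg adjustment, cross-contrast concordance (Pearson
    correlation and sign chi-square), hypergeometric over-representation of
    differentially methylated gene lists in functional, cytogenetic-band and
    transcription-factor-target gene sets, methylation-expression integration
    by gene symbol, and array-versus-pyrosequencing platform comparison. A
    bundled synthetic-data generator emulates the 8-donor early/late-passage,
    young/elderly study design with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
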