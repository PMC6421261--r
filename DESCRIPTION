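Package: refpanel
Title: Reference Gene Panel Selection for RT-qPCR from Transcriptome Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcriptome-wide screening and validation of RT-qPCR
    housekeeping (reference) genes, built around a from-scratch
    implementation of the geNorm stability algorithm. Provides abundance
    and detectability filtering of log2-scale expression matrices,
    iterative gene-stability ranking (stability measure M), pairwise
    variation V(n,n+1) for choosing the panel size, geometric-mean
    normalization factors, delta-Ct marker analysis with limit-of-detection
    handling of technical replicates, Pearson correlation comparison of
    normalization factors with Fisher-z confidence intervals, and
    hypergeometric over-representation analysis of the most stable genes
    against user-supplied gene sets. Includes a synthetic-data generator
    that emulates a multi-condition cellular senescence study design with
    planted stable genes for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
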