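Package: pairedconcord
Title: Concordance Analysis of Paired Tumour Biopsy Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying agreement between gene expression profiles
    of paired tumour biopsies, as arises in window-of-opportunity breast
    cancer trials and peri-surgical sampling studies. Provides microarray-style
    preprocessing (detection-fraction QC, quantile normalization, batch
    centering), within-pair and per-gene correlation analysis, dendrogram
    pair-adjacency concordance, paired differential expression with sign-flip
    permutation tests and Benjamini-Hochberg FDR control, weighted-average
    gene-signature scoring, nearest-centroid intrinsic subtyping with
    centroid-correlation margin diagnostics, Fisher r-to-z comparison of
    correlations across studies, and a paired-cohort simulator with known
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
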