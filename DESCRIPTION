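Package: rocscreen
Title: Drug-Sensitivity Biomarker Ranking for Cancer Cell-Line Screens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Engine for linking transcriptome-level gene expression to drug
    sensitivity across cancer cell-line screening cohorts. Normalizes
    read-count or pre-normalized expression matrices (median-of-ratios size
    factors, quantile normalization, per-cell-line scaling to a fixed mean),
    classifies cell lines as sensitive or resistant from IC50/AUDRC tertiles
    or medians, ranks single-gene and mean-signature biomarkers by ROC AUC,
    Mann-Whitney and Spearman statistics with Benjamini-Hochberg FDR, builds
    random-forest gene signatures with stratified held-out evaluation, ranks
    cell-line models by standardized AUDRC, reports cross-dataset overlaps,
    and generates fully synthetic multi-dataset cohorts with planted
    biomarker effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    DESeq2,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
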