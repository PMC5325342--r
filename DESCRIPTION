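Package: glioVPA
Title: Integrative RNA-Seq/ChIP-Seq Analysis of Valproic Acid Response in Glioma Cell Lines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterise transcriptional responses to
    valproic acid (VPA) in panels of glioma cell lines profiled without
    replicates. Implements the Audic-Claverie exact test for unreplicated
    count data, per-line pairwise differential expression with fold-change
    and BH adjustment, strand-aware promoter windows and ChIP-enriched
    region overlap calls (promoter euchromatinization), cross-line consensus
    signatures with two-lineage majority support, gene-family enrichment,
    a permutation-based gene set enrichment analysis (ES/NES/FDR),
    mesenchymal/proneural subtype scoring with an exact Wilcoxon
    signed-rank test, four-parameter logistic dose-response fitting with
    IC50 sensitization statistics, siRNA rescue normalization and
    delta-delta-Ct fold changes, plus seeded synthetic-data generators with
    ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Epigenetics, DifferentialExpression,
    GeneSetEnrichment, Pharmacogenomics
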