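Package: scnpair
Title: Paired Comparison of Single-Cell and Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for donor-paired comparisons of single-cell
    (scRNA-seq) and single-nucleus (snRNA-seq) transcriptomes, built around
    the human pancreatic islet setting. Provides CellRanger-style sparse
    matrix input/output, a quality-control filter cascade (feature
    prevalence, doublet removal, feature/count/complexity/mitochondrial/
    ribosomal thresholds), log-normalization and Wilcoxon rank-sum marker
    discovery with percent-detected and log2 fold-change gates, UMI-threshold
    gene-detection partitions between modalities, cell-type annotation
    concordance metrics (asymmetric overlap, per-type and weighted Jaccard),
    and donor-level paired statistics (exact Wilcoxon signed-rank,
    Hodges-Lehmann shift, percentile bootstrap confidence intervals,
    Benjamini-Hochberg adjustment). A synthetic paired-modality UMI
    generator with ambient contamination, doublets, and gene-class detection
    bias provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
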