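#' Quality-control thresholds for the barcode filter cascade
#'
#' Defaults mirror a standard droplet QC recipe: drop genes seen in fewer
#' than 10 barcodes per sample, then barcodes with fewer than 200 features,
#' then flagged doublets, then barcodes with fewer than 500 features, fewer
#' than 500 counts, complexity (log10 features / log10 counts) below 0.80,
#' mitochondrial fraction above 5% or ribosomal fraction above 35%; MALAT1
#' is removed from the matrix last.
#'
#' @param min_barcodes_per_feature,min_features_initial,min_features,
#'   min_counts Integer minima.
#' @param min_complexity Minimum log10(features)/log10(counts); the rule is
#'   strictly "below", so a barcode at exactly the threshold is retained.
#' @param max_mito_fraction,max_ribo_fraction Upper fraction bounds
#'   (strictly "above" fails).
#' @param remove_genes Gene ids dropped from the matrix after filtering.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_barcodes_per_feature = 10L,
                          min_features_initial = 200L,
                          min_features = 500L,
                          min_counts = 500L,
                          min_complexity = 0.80,
                          max_mito_fraction = 0.05,
                          max_ribo_fraction = 0.35,
                          remove_genes = "MALAT1") {
  stopifnot(min_barcodes_per_feature >= 0, min_features_initial >= 0,
            min_features >= 0, min_counts >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            max_ribo_fraction >= 0, max_ribo_fraction <= 1)
  structure(list(min_barcodes_per_feature = min_barcodes_per_feature,
                 min_features_initial = min_features_initial,
                 min_features = min_features, min_counts = min_counts,
                 min_complexity = min_complexity,
                 max_mito_fraction = max_mito_fraction,
                 max_ribo_fraction = max_ribo_fraction,
                 remove_genes = remove_genes),
            class = "qc_thresholds")
}

#' Default mitochondrial / ribosomal gene pickers
#'
#' Symbol-prefix helpers for building explicit gene lists: mitochondrial
#' genes start with `MT-`, ribosomal protein genes with `RPL` or `RPS`.
#'
#' @param genes Character vector of gene ids.
#' @return Character subset of `genes`.
#' @export
mito_genes_by_prefix <- function(genes) genes[startsWith(genes, "MT-")]

#' @rdname mito_genes_by_prefix
#' @export
ribo_genes_by_prefix <- function(genes) {
  genes[startsWith(genes, "RPL") | startsWith(genes, "RPS")]
}

#' Compute per-barcode QC metrics
#'
#' `n_features` counts genes with at least one UMI; `complexity` is
#' log10(n_features)/log10(n_counts), undefined (NA) when `n_counts < 2` or
#' no feature is detected; mito/ribo fractions are computed over total
#' counts including every gene present in the matrix.
#'
#' @param m Sparse genes x barcodes count matrix.
#' @param mito_genes,ribo_genes Explicit gene-id sets; ids absent from the
#'   matrix trigger a warning, not an error.
#' @return A data.frame with one row per barcode: `barcode`, `n_features`,
#'   `n_counts`, `complexity`, `mito_fraction`, `ribo_fraction`.
#' @export
compute_barcode_metrics <- function(m, mito_genes = character(0),
                                    ribo_genes = character(0)) {
  for (nm in list(mito = mito_genes, ribo = ribo_genes)) {
    miss <- setdiff(nm, rownames(m))
    if (length(miss)) {
      warning("gene set ids not in matrix: ",
              paste(utils::head(miss, 5), collapse = ", "))
    }
  }
  n_counts <- Matrix::colSums(m)
  n_features <- Matrix::colSums(m > 0)
  complexity <- ifelse(n_counts >= 2 & n_features >= 1,
                       log10(n_features) / log10(n_counts), NA_real_)
  sub_sum <- function(set) {
    set <- intersect(set, rownames(m))
    if (!length(set)) return(rep(0, ncol(m)))
    Matrix::colSums(m[set, , drop = FALSE])
  }
  mito_fraction <- ifelse(n_counts > 0, sub_sum(mito_genes) / n_counts, 0)
  ribo_fraction <- ifelse(n_counts > 0, sub_sum(ribo_genes) / n_counts, 0)
  data.frame(barcode = colnames(m), n_features = as.integer(n_features),
             n_counts = as.integer(n_counts), complexity = complexity,
             mito_fraction = mito_fraction, ribo_fraction = ribo_fraction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the QC filter cascade to one sample
#'
#' Stages, in order: (1) drop genes present (count >= 1) in fewer than
#' `min_barcodes_per_feature` barcodes; (2) drop barcodes with fewer than
#' `min_features_initial` features (computed on the gene-filtered matrix);
#' (3) drop flagged doublets; (4) recompute metrics and drop barcodes
#' failing any of the feature/count/complexity/mito/ribo thresholds; (5)
#' drop `remove_genes` from the matrix. The gene-prevalence rule is a single
#' pass and is not re-applied after barcode removal. Every removed barcode
#' carries all reasons that applied, not just the first.
#'
#' @param m Sparse genes x barcodes count matrix for one sample.
#' @param doublet_flag Logical vector (or named by barcode) marking
#'   predicted doublets.
#' @param thresholds A [qc_thresholds()].
#' @param mito_genes,ribo_genes Explicit gene sets for the fraction metrics.
#' @return List with `matrix` (filtered), `records` (per-input-barcode
#'   data.frame with metrics, `kept`, and a `removal_reasons` string, empty
#'   iff retained), and `stage_counts` (barcodes surviving each stage).
#' @export
apply_filters <- function(m, doublet_flag, thresholds = qc_thresholds(),
                          mito_genes = mito_genes_by_prefix(rownames(m)),
                          ribo_genes = ribo_genes_by_prefix(rownames(m))) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (!is.null(names(doublet_flag))) {
    doublet_flag <- doublet_flag[colnames(m)]
  }
  stopifnot(length(doublet_flag) == ncol(m))
  t <- thresholds

  gene_keep <- Matrix::rowSums(m > 0) >= t$min_barcodes_per_feature
  mg <- m[gene_keep, , drop = FALSE]

  metrics <- compute_barcode_metrics(mg, mito_genes, ribo_genes)
  reasons <- vector("list", ncol(m))
  add <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  fail_init <- metrics$n_features < t$min_features_initial
  add(fail_init, "low_features_initial")
  fail_dbl <- as.logical(doublet_flag)
  add(fail_dbl, "doublet")

  thresh_scope <- !fail_init & !fail_dbl
  fail_feat <- metrics$n_features < t$min_features
  fail_cnt <- metrics$n_counts < t$min_counts
  fail_cplx <- is.na(metrics$complexity) |
    metrics$complexity < t$min_complexity
  # complexity undefined only when counts < 2, which already fails min_counts
  fail_cplx[is.na(metrics$complexity)] <- TRUE
  fail_mito <- metrics$mito_fraction > t$max_mito_fraction
  fail_ribo <- metrics$ribo_fraction > t$max_ribo_fraction
  add(thresh_scope & fail_feat, "low_features")
  add(thresh_scope & fail_cnt, "low_counts")
  add(thresh_scope & fail_cplx, "low_complexity")
  add(thresh_scope & fail_mito, "high_mito")
  add(thresh_scope & fail_ribo, "high_ribo")

  kept <- vapply(reasons, length, integer(1)) == 0L
  out <- mg[setdiff(rownames(mg), t$remove_genes), kept, drop = FALSE]
  if (!any(kept)) warning("all barcodes removed by QC thresholds")

  metrics$doublet_flag <- fail_dbl
  metrics$kept <- kept
  metrics$removal_reasons <- vapply(
    reasons, function(r) paste(r, collapse = ";"), character(1))
  list(matrix = out, records = metrics,
       stage_counts = c(input = ncol(m),
                        after_initial = sum(!fail_init),
                        after_doublets = sum(!fail_init & !fail_dbl),
                        after_thresholds = sum(kept)))
}

#' Summarize one sample's retained barcodes
#'
#' Median and quartiles (type-7 linear interpolation) of counts, features,
#' complexity and mito/ribo fractions over retained barcodes, with sample
#' metadata (intronic/ambient/doublet fractions) passed through verbatim.
#'
#' @param records Barcode records from [apply_filters()].
#' @param sample_meta One-row data.frame (or list) of pass-through metadata;
#'   may be NULL.
#' @return A one-row data.frame.
#' @export
summarize_sample <- function(records, sample_meta = NULL) {
  kept <- records[records$kept, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no retained barcodes to summarize")
  q3 <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
    stats::setNames(as.numeric(q), c("q1", "median", "q3"))
  }
  out <- data.frame(n_barcodes_in = nrow(records),
                    n_barcodes_out = nrow(kept))
  for (metric in c("n_counts", "n_features", "complexity",
                   "mito_fraction", "ribo_fraction")) {
    q <- q3(kept[[metric]])
    out[[paste0(metric, "_q1")]] <- q[["q1"]]
    out[[paste0(metric, "_median")]] <- q[["median"]]
    out[[paste0(metric, "_q3")]] <- q[["q3"]]
  }
  if (!is.null(sample_meta)) {
    for (nm in setdiff(names(sample_meta), names(out))) {
      out[[nm]] <- sample_meta[[nm]]
    }
  }
  out
}
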