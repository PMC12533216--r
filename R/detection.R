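#' Parameters for the UMI-threshold expression rule
#'
#' A gene counts as expressed when at least one barcode in scope carries
#' `min_umi` or more UMIs (default 3); the prevalence variant requires that
#' in at least `prevalence_threshold` of the scoped barcodes (default 10%).
#'
#' @param min_umi Minimum UMI count (>= 1).
#' @param prevalence_threshold Fraction of barcodes in `[0, 1]`.
#' @return A `detection_params` list.
#' @export
detection_params <- function(min_umi = 3L, prevalence_threshold = 0.10) {
  stopifnot(min_umi >= 1, prevalence_threshold >= 0,
            prevalence_threshold <= 1)
  structure(list(min_umi = as.integer(min_umi),
                 prevalence_threshold = prevalence_threshold),
            class = "detection_params")
}

#' Genes detected under the UMI-threshold rule
#'
#' @param m Sparse genes x barcodes raw count matrix (post-QC).
#' @param params A [detection_params()].
#' @param scope Barcode subset (names or indices); defaults to all.
#' @param prevalence If TRUE, require detection in at least
#'   `prevalence_threshold` of the scoped barcodes instead of just one.
#' @return Character vector of detected gene ids.
#' @export
detected_genes <- function(m, params = detection_params(), scope = NULL,
                           prevalence = FALSE) {
  if (!is.null(scope)) m <- m[, scope, drop = FALSE]
  if (ncol(m) == 0L) stop("scope is empty")
  hits <- Matrix::rowSums(m >= params$min_umi)
  need <- if (prevalence) params$prevalence_threshold * ncol(m) else 1
  rownames(m)[hits >= need]
}

#' Partition the gene universe by modality detection
#'
#' Set algebra over [detected_genes()] of two matrices sharing a gene
#' universe; percentages are reported relative to the union, rounded
#' half-up to the nearest percent as in printed summaries.
#'
#' @param m_a,m_b Count matrices for the two modalities (e.g. cells and
#'   nuclei) with identical rownames.
#' @param params A [detection_params()].
#' @param prevalence Use the prevalence variant of the rule.
#' @return A `detection_partition` list: counts `n_union`, `n_both`,
#'   `n_only_a`, `n_only_b`; rounded percentages `pct_both`, `pct_only_a`,
#'   `pct_only_b`; and a per-gene membership data.frame.
#' @export
partition_by_modality <- function(m_a, m_b, params = detection_params(),
                                  prevalence = FALSE) {
  if (!identical(rownames(m_a), rownames(m_b))) {
    stop("matrices must share an identical gene universe")
  }
  in_a <- rownames(m_a) %in%
    detected_genes(m_a, params, prevalence = prevalence)
  in_b <- rownames(m_b) %in%
    detected_genes(m_b, params, prevalence = prevalence)
  detection_partition(rownames(m_a), in_a, in_b)
}

#' Build a detection partition from membership flags
#'
#' @param genes Gene ids.
#' @param in_a,in_b Logical detection flags per gene.
#' @return A `detection_partition` list; the conservation identity
#'   `n_union = n_both + n_only_a + n_only_b` is asserted on every call.
#' @export
detection_partition <- function(genes, in_a, in_b) {
  n_both <- sum(in_a & in_b)
  n_only_a <- sum(in_a & !in_b)
  n_only_b <- sum(!in_a & in_b)
  n_union <- sum(in_a | in_b)
  stopifnot(n_union == n_both + n_only_a + n_only_b)
  pct <- function(n) round_half_up(100 * n / n_union)
  structure(list(n_union = n_union, n_both = n_both,
                 n_only_a = n_only_a, n_only_b = n_only_b,
                 pct_both = pct(n_both), pct_only_a = pct(n_only_a),
                 pct_only_b = pct(n_only_b),
                 membership = data.frame(gene = genes, in_a = in_a,
                                         in_b = in_b,
                                         stringsAsFactors = FALSE)),
            class = "detection_partition")
}

#' Detection rate of a gene within a barcode group
#'
#' Fraction of barcodes in the group where the gene has at least `min_umi`
#' UMIs (the "expressed" rule).
#'
#' @param m Sparse genes x barcodes raw count matrix.
#' @param gene Gene id (must be present).
#' @param group Barcode subset (names or indices); defaults to all.
#' @param params A [detection_params()].
#' @return Proportion in `[0, 1]`.
#' @export
detection_rate <- function(m, gene, group = NULL,
                           params = detection_params()) {
  if (!gene %in% rownames(m)) stop("unknown gene: ", gene)
  if (!is.null(group)) m <- m[, group, drop = FALSE]
  if (ncol(m) == 0L) stop("group is empty")
  mean(m[gene, ] >= params$min_umi)
}
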