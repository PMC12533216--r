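#' Parameters for marker-gene discovery
#'
#' @param min_pct Minimum fraction of barcodes in the tested group detecting
#'   the gene (count >= 1): 0.25 for the loose cluster-marker pass, 0.50 for
#'   the strict cell-type-marker pass.
#' @param min_log2fc Log2 fold-change gate (default 1): genes are screened
#'   at `|avg_log2FC| >= min_log2fc` before testing, and the gated marker
#'   set additionally requires `avg_log2FC > min_log2fc`.
#' @param max_fdr BH-adjusted significance gate (default 0.05, strict `<`).
#' @param scale_factor Library-size scale for [log_normalize()].
#' @param pseudocount Added inside the log2 fold-change means.
#' @return A `marker_params` list.
#' @export
marker_params <- function(min_pct = 0.25, min_log2fc = 1.0, max_fdr = 0.05,
                          scale_factor = 1e4, pseudocount = 1.0) {
  stopifnot(min_pct >= 0, min_pct <= 1, scale_factor > 0, pseudocount > 0)
  structure(list(min_pct = min_pct, min_log2fc = min_log2fc,
                 max_fdr = max_fdr, scale_factor = scale_factor,
                 pseudocount = pseudocount),
            class = "marker_params")
}

#' Log-normalize a UMI matrix
#'
#' Each entry becomes `ln(1 + count / barcode_total * scale_factor)`;
#' zeros stay zero, so sparsity is preserved.
#'
#' @param m Sparse genes x barcodes count matrix, no zero-total barcodes.
#' @param scale_factor Positive scale (default 10000).
#' @return Sparse normalized matrix of the same shape.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  m <- methods::as(m, "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) {
    stop("zero-total barcode(s): ",
         paste(utils::head(colnames(m)[totals == 0], 5), collapse = ", "))
  }
  per_entry <- rep.int(totals, diff(m@p))
  m@x <- log1p(m@x / per_entry * scale_factor)
  m
}

# Exact two-sided rank-sum p-value under the permutation null, respecting
# ties through midranks. The distribution of the group rank-sum over all
# C(N, n1) subsets is built by subset-sum dynamic programming on doubled
# midranks (integers), which is equivalent to full enumeration.
rank_sum_exact_p <- function(r1, r_all, n1) {
  d <- as.integer(round(2 * r_all))
  w <- sum(round(2 * r1))
  maxs <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
  # dp[k+1, s+1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = n1 + 1L, ncol = maxs + 1L)
  dp[1L, 1L] <- 1
  for (v in d) {
    kmax <- n1
    for (k in kmax:1) {
      idx <- seq_len(maxs + 1L - v)
      dp[k + 1L, idx + v] <- dp[k + 1L, idx + v] + dp[k, idx]
    }
  }
  counts <- dp[n1 + 1L, ]
  total <- sum(counts)
  sums <- seq(0L, maxs)
  p_le <- sum(counts[sums <= w]) / total
  p_ge <- sum(counts[sums >= w]) / total
  min(1, 2 * min(p_le, p_ge))
}

# Normal-approximation two-sided rank-sum p with midrank tie correction and
# continuity correction.
rank_sum_normal_p <- function(r1, r_all, n1) {
  N <- length(r_all)
  n2 <- N - n1
  w <- sum(r1)
  mu <- n1 * (N + 1) / 2
  ties <- table(r_all)
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses the exact tie-respecting permutation distribution (dynamic
#' programming over midranks) when the pooled size is at most `exact_max_n`,
#' and the normal approximation with tie and continuity corrections above
#' that. A constant pooled vector (all ties) gives p = 1.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_max_n Pooled-size cutover between exact and approximate.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y, exact_max_n = 50L) {
  z <- c(x, y)
  if (length(unique(z)) <= 1L) return(1)
  r <- rank(z)
  n1 <- length(x)
  r1 <- r[seq_len(n1)]
  if (length(z) <= exact_max_n) {
    rank_sum_exact_p(r1, r, n1)
  } else {
    rank_sum_normal_p(r1, r, n1)
  }
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH with monotonicity enforcement, mapped back to input order
#' (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return FDR vector aligned with `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Group-vs-rest marker testing with detection and fold-change gates
#'
#' For each group, genes are screened to those detected (count >= 1) in at
#' least `min_pct` of the group's barcodes with `|avg_log2FC| >= min_log2fc`
#' where `avg_log2FC = log2(mean(expm1(x_group)) + pseudocount) -
#' log2(mean(expm1(x_rest)) + pseudocount)`; surviving genes get a
#' two-sided Wilcoxon rank-sum test on normalized values and BH adjustment
#' within the group's tested family. The gated marker set keeps rows with
#' `fdr < max_fdr` and `avg_log2FC > min_log2fc` (positive markers).
#'
#' @param norm Log-normalized genes x barcodes matrix.
#' @param groups Barcode group labels (vector aligned with columns, or named
#'   by barcode).
#' @param params A [marker_params()].
#' @param mode `"one_vs_rest"` tests every group against the pooled
#'   complement; `"pairwise"` requires exactly two groups and tests the
#'   first against the second.
#' @param positive_only Screen on `avg_log2FC >= min_log2fc` instead of the
#'   absolute value.
#' @param pct2_mode Complement detection fraction: `"pooled"` over all
#'   other barcodes (default) or `"per_type_mean"`, the unweighted mean of
#'   per-group detection fractions.
#' @return Data.frame with columns `gene`, `group`, `p_value`, `fdr`,
#'   `avg_log2FC`, `pct1`, `pct2`, `n_group`, `n_rest`, `is_marker`.
#' @export
find_markers <- function(norm, groups, params = marker_params(),
                         mode = c("one_vs_rest", "pairwise"),
                         positive_only = FALSE,
                         pct2_mode = c("pooled", "per_type_mean")) {
  mode <- match.arg(mode)
  pct2_mode <- match.arg(pct2_mode)
  if (!is.null(names(groups))) groups <- groups[colnames(norm)]
  stopifnot(length(groups) == ncol(norm))
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  if (mode == "pairwise" && length(lev) != 2L) {
    stop("pairwise mode requires exactly 2 groups")
  }
  test_groups <- if (mode == "pairwise") lev[1L] else lev

  res <- list()
  for (g in test_groups) {
    idx_g <- which(groups == g)
    idx_r <- which(groups != g)
    if (length(idx_g) < 3L) stop("group ", g, " has fewer than 3 barcodes")
    xg <- norm[, idx_g, drop = FALSE]
    xr <- norm[, idx_r, drop = FALSE]
    pct1 <- Matrix::rowMeans(xg > 0)
    pct2 <- if (pct2_mode == "pooled") {
      Matrix::rowMeans(xr > 0)
    } else {
      other <- setdiff(lev, g)
      rowMeans(vapply(other, function(h) {
        Matrix::rowMeans(norm[, groups == h, drop = FALSE] > 0)
      }, numeric(nrow(norm))))
    }
    mg <- Matrix::rowMeans(expm1_sparse(xg))
    mr <- Matrix::rowMeans(expm1_sparse(xr))
    fc <- log2(mg + params$pseudocount) - log2(mr + params$pseudocount)

    screen <- pct1 >= params$min_pct &
      (if (positive_only) fc >= params$min_log2fc
       else abs(fc) >= params$min_log2fc)
    tested <- which(screen)
    if (!length(tested)) next
    sub <- as.matrix(norm[tested, c(idx_g, idx_r), drop = FALSE])
    ng <- length(idx_g)
    p <- apply(sub, 1L, function(v) {
      rank_sum_test(v[seq_len(ng)], v[-seq_len(ng)])
    })
    fdr <- benjamini_hochberg(p)
    res[[g]] <- data.frame(
      gene = rownames(norm)[tested], group = g, p_value = p, fdr = fdr,
      avg_log2FC = fc[tested], pct1 = pct1[tested], pct2 = pct2[tested],
      n_group = length(idx_g), n_rest = length(idx_r),
      is_marker = fdr < params$max_fdr & fc[tested] > params$min_log2fc,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(gene = character(0), group = character(0),
                      p_value = numeric(0), fdr = numeric(0),
                      avg_log2FC = numeric(0), pct1 = numeric(0),
                      pct2 = numeric(0), n_group = integer(0),
                      n_rest = integer(0), is_marker = logical(0)))
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}

# expm1 on a sparse matrix without densifying (expm1(0) = 0).
expm1_sparse <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  m@x <- expm1(m@x)
  m
}

#' Overlap between two gene lists
#'
#' @param list_a,list_b Character gene sets (may be empty).
#' @param denominator `"jaccard"` (intersection over union), `"a"`
#'   (intersection over `|A|`) or `"b"`.
#' @return Proportion in `[0, 1]`, or NA when the denominator is empty.
#' @export
marker_list_overlap <- function(list_a, list_b,
                                denominator = c("jaccard", "a", "b")) {
  denominator <- match.arg(denominator)
  a <- unique(list_a); b <- unique(list_b)
  i <- length(intersect(a, b))
  den <- switch(denominator,
                jaccard = length(union(a, b)),
                a = length(a),
                b = length(b))
  if (den == 0L) return(NA_real_)
  i / den
}
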