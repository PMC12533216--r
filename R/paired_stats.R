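#' Aggregate per-barcode metrics to one value per donor and modality
#'
#' Per-barcode measurements are collapsed to a per-donor average (or median)
#' within each modality before testing, to avoid pseudo-replication; the
#' paired difference is always nucleus minus cell, so negative shifts mean
#' lower values in snRNA-seq.
#'
#' @param records Data.frame with `donor_id`, `modality` and the metric
#'   column.
#' @param metric Column name to aggregate.
#' @param statistic `"mean"` or `"median"`.
#' @return Data.frame with `donor_id`, `value_cell`, `value_nucleus`,
#'   `difference`; donors lacking either modality are dropped with a
#'   warning.
#' @export
aggregate_per_donor <- function(records, metric,
                                statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(metric %in% names(records))
  f <- if (statistic == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) stats::median(x, na.rm = TRUE)
  }
  agg <- stats::aggregate(records[[metric]],
                          by = list(donor_id = records$donor_id,
                                    modality = records$modality),
                          FUN = f)
  wide <- merge(agg[agg$modality == "cell", c("donor_id", "x")],
                agg[agg$modality == "nucleus", c("donor_id", "x")],
                by = "donor_id", suffixes = c("_cell", "_nucleus"))
  dropped <- setdiff(unique(records$donor_id), wide$donor_id)
  if (length(dropped)) {
    warning("donors without both modalities dropped: ",
            paste(dropped, collapse = ", "))
  }
  names(wide) <- c("donor_id", "value_cell", "value_nucleus")
  wide$difference <- wide$value_nucleus - wide$value_cell
  wide[order(wide$donor_id), , drop = FALSE]
}

#' Hodges-Lehmann location shift of paired differences
#'
#' `"walsh"` (the classical HL estimator) is the median of all
#' `n(n+1)/2` Walsh averages `(d_i + d_j)/2` with `i <= j`;
#' `"plain_median"` is the median of the differences themselves.
#'
#' @param differences Numeric vector of paired (nucleus minus cell)
#'   differences.
#' @param estimator `"walsh"` or `"plain_median"`.
#' @return The location estimate.
#' @export
hl_shift <- function(differences, estimator = c("walsh", "plain_median")) {
  estimator <- match.arg(estimator)
  d <- differences[!is.na(differences)]
  if (!length(d)) stop("no differences supplied")
  if (estimator == "plain_median") return(stats::median(d))
  n <- length(d)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  stats::median((d[idx[, 1L]] + d[idx[, 2L]]) / 2)
}

# Exact two-sided signed-rank p via subset-sum dynamic programming over
# doubled midranks of |d| (equivalent to enumerating all 2^n sign vectors).
signed_rank_exact_p <- function(r) {
  d <- as.integer(round(2 * abs(r)))
  w <- sum(d[r > 0]) # doubled W+
  tot <- sum(d)
  counts <- numeric(tot + 1L)
  counts[1L] <- 1
  for (v in d) {
    shifted <- c(rep(0, v), counts[seq_len(tot + 1L - v)])
    counts <- counts + shifted
  }
  total <- 2^length(d)
  sums <- seq(0L, tot)
  p_le <- sum(counts[sums <= w]) / total
  p_ge <- sum(counts[sums >= w]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sided paired Wilcoxon signed-rank test on differences
#'
#' Zeros are dropped before ranking; absolute differences get midranks.
#' For `n <= exact_max_n` remaining pairs the exact null distribution over
#' all `2^n` sign assignments is used (computed by dynamic programming,
#' which enumerates the same distribution in polynomial time); above that,
#' a normal approximation with tie correction and continuity correction.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_max_n Cutover between exact and approximate (default 25).
#' @return Two-sided p-value; all-zero input gives p = 1 with a warning.
#' @export
wilcoxon_signed_rank <- function(differences, exact_max_n = 25L) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  if (!length(d)) {
    warning("all differences are zero")
    return(1)
  }
  if (length(d) < 2L) stop("need at least 2 nonzero differences")
  r <- rank(abs(d)) * sign(d)
  if (length(d) <= exact_max_n) {
    signed_rank_exact_p(r)
  } else {
    n <- length(d)
    w <- sum(r[r > 0])
    mu <- n * (n + 1) / 4
    ties <- table(abs(r))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) return(1)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Percentile bootstrap confidence interval for the HL shift
#'
#' Donor pairs are the unit of resampling: differences are resampled with
#' replacement and the HL estimate recomputed per resample; the interval is
#' the empirical `(1 - level)/2` and `1 - (1 - level)/2` percentiles
#' (type-7 quantiles). Deterministic given the seed.
#'
#' @param differences Paired differences (one per donor).
#' @param estimator Passed to [hl_shift()].
#' @param resamples Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(differences, estimator = "walsh",
                         resamples = 10000L, level = 0.95, seed = 1L) {
  d <- differences[!is.na(differences)]
  stopifnot(length(d) >= 2L, resamples >= 1L)
  set.seed(seed)
  est <- vapply(seq_len(resamples), function(i) {
    hl_shift(sample(d, length(d), replace = TRUE), estimator)
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(est, c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(ci_low = q[1L], ci_high = q[2L])
}

#' Paired donor-level comparison of one metric between modalities
#'
#' @param pairs Data.frame from [aggregate_per_donor()] (needs a
#'   `difference` column), or a numeric difference vector.
#' @param metric Metric name carried into the result.
#' @param estimator `"walsh"` (default) or `"plain_median"`.
#' @param resamples,level,seed Bootstrap settings, see [bootstrap_ci()].
#' @param family Family tag for BH adjustment across metrics.
#' @return One-row data.frame: `metric`, `n_pairs`, `hl_shift`, `ci_low`,
#'   `ci_high`, `p_value`, `fdr` (NA until [family_adjust()]), `estimator`,
#'   `resamples`, `seed`, `family`.
#' @export
paired_modality_test <- function(pairs, metric = "metric",
                                 estimator = "walsh", resamples = 10000L,
                                 level = 0.95, seed = 1L,
                                 family = "default") {
  d <- if (is.data.frame(pairs)) pairs$difference else as.numeric(pairs)
  if (length(d) < 2L) stop("need at least 2 complete donor pairs")
  est <- hl_shift(d, estimator)
  ci <- bootstrap_ci(d, estimator, resamples, level, seed)
  if (est < ci[["ci_low"]] || est > ci[["ci_high"]]) {
    message("percentile CI excludes the point estimate for ", metric,
            " (possible at very small n)")
  }
  data.frame(metric = metric, n_pairs = length(d), hl_shift = est,
             ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
             p_value = wilcoxon_signed_rank(d), fdr = NA_real_,
             estimator = estimator, resamples = as.integer(resamples),
             seed = as.integer(seed), family = family,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment within declared families
#'
#' @param results Data.frame of [paired_modality_test()] rows with
#'   `p_value` and `family` columns.
#' @return The same data.frame with `fdr` filled in per family.
#' @export
family_adjust <- function(results) {
  stopifnot(all(c("p_value", "family") %in% names(results)))
  for (fam in unique(results$family)) {
    idx <- results$family == fam
    results$fdr[idx] <- benjamini_hochberg(results$p_value[idx])
  }
  results
}
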