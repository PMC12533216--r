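make_counts <- function(mat, genes = NULL, barcodes = NULL) {
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(mat)))
  if (is.null(barcodes)) barcodes <- paste0("B", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, barcodes)
  methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
}

test_that("barcode metrics match their closed forms", {
  # 10 genes detected, 100 total counts -> complexity 0.5
  m <- make_counts(matrix(c(rep(10, 10), rep(0, 2)), ncol = 1),
                   genes = c(paste0("G", 1:9), "MT-1", "RPL1", "RPS1"))
  met <- compute_barcode_metrics(m, "MT-1", c("RPL1", "RPS1"))
  expect_equal(met$n_features, 10L)
  expect_equal(met$n_counts, 100L)
  expect_equal(met$complexity, 0.5)
  expect_equal(met$mito_fraction, 0.10)

  # 5 of 100 counts on mito genes -> mito fraction 0.05
  m2 <- make_counts(matrix(c(5, 95), ncol = 1), genes = c("MT-1", "G1"))
  expect_equal(compute_barcode_metrics(m2, "MT-1")$mito_fraction, 0.05)

  # zero-count barcode: metrics defined, complexity NA, no error
  m3 <- make_counts(matrix(0, 3, 1))
  met3 <- compute_barcode_metrics(m3)
  expect_equal(met3$n_counts, 0L)
  expect_true(is.na(met3$complexity))
  expect_equal(met3$mito_fraction, 0)

  expect_warning(compute_barcode_metrics(m2, "MT-ABSENT"), "not in matrix")
})

test_that("metrics equal a dense brute-force recomputation", {
  m <- rand_counts(60, 40, seed = 3, lambda = 1.5)
  rownames(m)[1:4] <- paste0("MT-", 1:4)
  rownames(m)[5:10] <- paste0("RPL", 1:6)
  d <- as.matrix(m)
  met <- compute_barcode_metrics(m, mito_genes_by_prefix(rownames(m)),
                                 ribo_genes_by_prefix(rownames(m)))
  expect_equal(met$n_features, as.integer(colSums(d > 0)))
  expect_equal(met$n_counts, as.integer(colSums(d)))
  expect_equal(met$mito_fraction, colSums(d[1:4, ]) / colSums(d),
               ignore_attr = TRUE)
  expect_equal(met$ribo_fraction, colSums(d[5:10, ]) / colSums(d),
               ignore_attr = TRUE)
  expect_equal(met$complexity,
               ifelse(colSums(d) >= 2, log10(colSums(d > 0)) /
                        log10(colSums(d)), NA_real_),
               ignore_attr = TRUE)
})

test_that("filter boundaries follow the strict/non-strict conventions", {
  # two barcodes: 499 features vs 500 features, everything else passing
  ng <- 600
  mat <- matrix(0, ng, 2)
  mat[1:499, 1] <- 3
  mat[1:500, 2] <- 3
  m <- make_counts(mat)
  t <- qc_thresholds(min_barcodes_per_feature = 0,
                     min_features_initial = 0, remove_genes = character(0))
  fl <- apply_filters(m, c(FALSE, FALSE), t)
  expect_false(fl$records$kept[1])
  expect_identical(fl$records$removal_reasons[1], "low_features")
  expect_true(fl$records$kept[2])

  # complexity exactly at the threshold is retained (rule is strictly below)
  # 10^(0.8 * log10(n_counts)) features with count spread to hit exactly
  nc <- 10000L; nf <- as.integer(round(10^(0.8 * log10(nc))))
  v <- rep(0L, 2000); v[seq_len(nf)] <- 1L
  v[1] <- v[1] + nc - nf
  mB <- make_counts(matrix(v, ncol = 1))
  met <- compute_barcode_metrics(mB)
  expect_gte(met$complexity, 0.8 - 1e-12)
  t2 <- qc_thresholds(min_barcodes_per_feature = 0,
                      min_features_initial = 0,
                      remove_genes = character(0))
  fl2 <- apply_filters(mB, FALSE, t2)
  expect_true(fl2$records$kept[1])
})

test_that("the cascade matches an independent boolean oracle", {
  set.seed(31)
  ng <- 300; nb <- 1000
  mat <- matrix(rpois(ng * nb, 2.2), ng, nb)
  # plant heterogeneity so every rule fires somewhere
  mat[, 1:60] <- 0L
  mat[1:12, ] <- matrix(rpois(12 * nb, 40), 12)   # mito-heavy rows
  m <- make_counts(mat)
  rownames(m)[1:12] <- paste0("MT-", 1:12)
  rownames(m)[13] <- "MALAT1"
  dbl <- seq_len(nb) %% 17 == 0
  t <- qc_thresholds(min_barcodes_per_feature = 5,
                     min_features_initial = 50, min_features = 150,
                     min_counts = 400, min_complexity = 0.80,
                     max_mito_fraction = 0.45, max_ribo_fraction = 0.35)
  fl <- apply_filters(m, dbl, t)

  # oracle: dense one-pass recomputation of the same cascade
  d <- as.matrix(m)
  gene_keep <- rowSums(d > 0) >= 5
  d2 <- d[gene_keep, ]
  nfeat <- colSums(d2 > 0); ncnt <- colSums(d2)
  cplx <- ifelse(ncnt >= 2 & nfeat >= 1, log10(nfeat) / log10(ncnt), NA)
  mito <- colSums(d2[startsWith(rownames(d2), "MT-"), , drop = FALSE]) /
    pmax(ncnt, 1)
  keep <- nfeat >= 50 & !dbl & nfeat >= 150 & ncnt >= 400 &
    !is.na(cplx) & cplx >= 0.80 & mito <= 0.45
  expect_identical(fl$records$kept, unname(keep))
  expect_identical(colnames(fl$matrix), colnames(d)[keep])
  expect_false("MALAT1" %in% rownames(fl$matrix))
  # removed barcodes carry every applicable reason
  r <- fl$records
  low_cnt <- !dbl & nfeat >= 50 & ncnt < 400
  expect_identical(grepl("low_counts", r$removal_reasons),
                   unname(low_cnt))
})

test_that("filtering is idempotent and monotone in thresholds", {
  sim <- shared_sim()
  m <- sim$samples[[1]]
  bc <- sim$barcodes[sim$barcodes$sample_id == names(sim$samples)[1], ]
  dbl <- stats::setNames(bc$is_doublet, bc$barcode)
  # keep MALAT1 in: its removal changes totals, so metric-bearing reruns
  # are only comparable on the cascade proper
  t <- qc_thresholds(remove_genes = character(0))
  fl <- apply_filters(m, dbl, t)
  again <- apply_filters(fl$matrix, dbl[colnames(fl$matrix)], t)
  expect_identical(colnames(again$matrix), colnames(fl$matrix))
  expect_identical(rownames(again$matrix), rownames(fl$matrix))

  tighter <- qc_thresholds(min_counts = 2000, max_mito_fraction = 0.03)
  fl2 <- apply_filters(m, dbl, tighter)
  expect_true(all(colnames(fl2$matrix) %in% colnames(fl$matrix)))

  # final matrix satisfies barcode thresholds on its own metrics
  met <- compute_barcode_metrics(fl$matrix,
                                 mito_genes_by_prefix(rownames(fl$matrix)),
                                 ribo_genes_by_prefix(rownames(fl$matrix)))
  expect_true(all(met$n_counts >= t$min_counts))
})

test_that("sample summaries use type-7 quantiles and pass metadata", {
  rec <- data.frame(barcode = paste0("b", 1:4), n_features = c(1, 2, 3, 4),
                    n_counts = c(10, 10, 10, 10), complexity = 0.9,
                    mito_fraction = 0.01, ribo_fraction = 0.1,
                    kept = TRUE, removal_reasons = "")
  s <- summarize_sample(rec, list(intronic_fraction = 0.54))
  expect_equal(s$n_features_median, 2.5)
  expect_equal(s$n_features_q1, 1.75)
  expect_equal(s$n_features_q3, 3.25)
  expect_equal(s$complexity_median, 0.9)
  expect_equal(s$complexity_q1, 0.9)
  expect_equal(s$intronic_fraction, 0.54)

  set.seed(5)
  rec2 <- rec[rep(1, 50), ]
  rec2$n_counts <- rpois(50, 800)
  s2 <- summarize_sample(rec2)
  expect_equal(s2$n_counts_median,
               unname(quantile(rec2$n_counts, 0.5, type = 7)))
  expect_equal(s2$n_counts_q3,
               unname(quantile(rec2$n_counts, 0.75, type = 7)))
})
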