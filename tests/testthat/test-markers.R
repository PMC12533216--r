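test_that("log-normalization matches its closed form and a dense oracle", {
  m <- rand_counts(30, 20, seed = 2, lambda = 1)
  m[1, 1] <- 50
  cs <- Matrix::colSums(m)
  norm <- log_normalize(m, 1e4)
  expect_equal(norm[1, 1], log(1 + 50 / cs[1] * 1e4), ignore_attr = TRUE)
  d <- as.matrix(m)
  expected <- log1p(sweep(d, 2, colSums(d), "/") * 1e4)
  expect_equal(as.matrix(norm), expected)
  expect_equal(sum(as.matrix(norm) == 0), sum(d == 0))

  # count 50 in a 10,000-total barcode at scale 10,000 -> ln(51)
  v <- rep(0L, 100); v[1] <- 50L; v[2] <- 9950L
  mm <- Matrix::Matrix(matrix(v, ncol = 1), sparse = TRUE,
                       dimnames = list(paste0("g", 1:100), "b"))
  expect_equal(log_normalize(mm)[1, 1], log(51), ignore_attr = TRUE)

  m0 <- Matrix::Matrix(matrix(c(1, 0), 1), sparse = TRUE,
                       dimnames = list("g", c("good", "empty")))
  expect_error(log_normalize(m0), "empty")
})

test_that("complete separation yields the minimal attainable exact p", {
  # value 2.0 in all 10 group barcodes, zero in all 20 rest
  x <- rep(2, 10); y <- rep(0, 20)
  expect_equal(rank_sum_test(x, y), 2 / choose(30, 10))
  # and the corresponding fold change on the normalized scale
  fc <- log2(mean(expm1(x)) + 1) - log2(mean(expm1(y)) + 1)
  expect_equal(fc, log2(exp(2) - 1 + 1), tolerance = 1e-12)
})

test_that("exact rank-sum agrees with wilcox.test when tie-free", {
  for (s in 1:25) {
    set.seed(s)
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(rank_sum_test(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("normal approximation tracks the exact p for small groups", {
  worst <- 0
  for (s in 1:40) {
    set.seed(100 + s)
    x <- rnorm(sample(5:10, 1)); y <- rnorm(sample(5:10, 1))
    z <- c(x, y); r <- rank(z)
    p_ex <- scnpair:::rank_sum_exact_p(r[seq_along(x)], r, length(x))
    p_ap <- scnpair:::rank_sum_normal_p(r[seq_along(x)], r, length(x))
    worst <- max(worst, abs(p_ex - p_ap))
  }
  expect_lte(worst, 0.02)
})

test_that("rank-sum test is calibrated under the null", {
  set.seed(314)
  n_reject <- 0
  for (i in 1:1000) {
    z <- rnorm(30)
    if (rank_sum_test(z[1:15], z[16:30]) < 0.05) n_reject <- n_reject + 1
  }
  expect_lte(n_reject / 1000, 0.06)
})

test_that("constant genes give p = 1", {
  expect_equal(rank_sum_test(rep(1, 5), rep(1, 8)), 1)
})

test_that("BH delegate matches an independent step-up implementation", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  p <- runif(20)
  expect_true(all(benjamini_hochberg(p) >= p))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("find_markers applies the pct and fold-change gates", {
  set.seed(7)
  ng <- 40
  mat <- matrix(rpois(ng * 60, 2), ng, 60)
  mat[1, 1:20] <- rpois(20, 30)     # strong group-1 marker
  mat[2, ] <- 0L
  mat[2, 1:7] <- 5L                 # detected in 35% of group 1
  m <- Matrix::Matrix(mat, sparse = TRUE,
                      dimnames = list(paste0("g", 1:ng),
                                      paste0("b", 1:60)))
  norm <- log_normalize(m)
  groups <- rep(c("A", "B", "C"), each = 20)
  res <- find_markers(norm, groups, marker_params(min_pct = 0.5))
  a <- res[res$group == "A", ]
  expect_true("g1" %in% a$gene[a$is_marker])
  expect_false("g2" %in% a$gene)     # pct1 = 0.35 < 0.5 screened out
  res2 <- find_markers(norm, groups, marker_params(min_pct = 0.25))
  expect_true("g2" %in% res2$gene[res2$group == "A"])

  # pct accounting: detected-in-39-of-100 semantics
  g2row <- res2[res2$group == "A" & res2$gene == "g2", ]
  expect_equal(g2row$pct1, 7 / 20)
  expect_equal(g2row$pct2, 0)
})

test_that("marker statistics are invariant to barcode order", {
  sim <- shared_sim()
  m <- sim$samples[[1]]
  bc <- sim$barcodes[sim$barcodes$sample_id == names(sim$samples)[1] &
                       !sim$barcodes$is_doublet, ]
  m <- m[, bc$barcode]
  keep_types <- names(which(table(bc$true_type) >= 10))[1:3]
  sel <- bc$true_type %in% keep_types
  m <- m[, sel]; grp <- bc$true_type[sel]
  norm <- log_normalize(m)
  r1 <- find_markers(norm, grp, marker_params(min_pct = 0.5))
  set.seed(1); perm <- sample(ncol(norm))
  r2 <- find_markers(norm[, perm], grp[perm], marker_params(min_pct = 0.5))
  r1 <- r1[order(r1$group, r1$gene), ]
  r2 <- r2[order(r2$group, r2$gene), ]
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$avg_log2FC, r2$avg_log2FC)
  expect_equal(r1$pct1, r2$pct1)
})

test_that("planted markers are recovered under the strict gates", {
  prof <- islet_profiles(n_types = 4, markers_per_type = 5, n_nuclear = 6,
                         n_mito = 4, n_ribo = 6, n_genes = 120,
                         enrichment_log2 = 2, hormone_share = 0.21)
  eff <- neutral_effect(prof, libsize_log_mean = 7.5)
  sim <- simulate_paired_dataset(
    n_donors = 1,
    composition = matrix(rep(0.25, 4), 1,
                         dimnames = list("d1", prof$types)),
    profiles = prof, effects = list(cell = eff, nucleus = eff),
    n_barcodes = 240, seed = 17)
  m <- sim$samples$d1_cell
  bc <- sim$barcodes[sim$barcodes$sample_id == "d1_cell", ]
  norm <- log_normalize(m)
  res <- find_markers(norm, stats::setNames(bc$true_type, bc$barcode),
                      marker_params(min_pct = 0.5))
  found <- res[res$is_marker, ]
  planted <- unlist(prof$markers)
  hit <- vapply(names(prof$markers), function(tt) {
    mean(prof$markers[[tt]] %in% found$gene[found$group == tt])
  }, numeric(1))
  expect_gte(mean(hit), 0.95)
  bg <- sim$gene_classes$gene[sim$gene_classes$class == "background"]
  expect_lte(mean(bg %in% found$gene), 0.01)
})

test_that("pairwise mode tests exactly two groups", {
  m <- rand_counts(20, 30, seed = 12, lambda = 3)
  norm <- log_normalize(m)
  grp <- rep(c("cell", "nucleus"), each = 15)
  res <- find_markers(norm, grp, marker_params(min_pct = 0,
                                               min_log2fc = 0),
                      mode = "pairwise")
  expect_true(all(res$group == "cell"))
  expect_error(find_markers(norm, rep(c("a", "b", "c"), each = 10),
                            mode = "pairwise"), "exactly 2")
  expect_error(find_markers(norm, rep("a", 30)), "at least 2")
})

test_that("gene-list overlap handles every denominator", {
  a <- paste0("g", 1:110); b <- paste0("g", 8:110)
  expect_equal(marker_list_overlap(a, a, "jaccard"), 1)
  expect_equal(marker_list_overlap(a, paste0("x", 1:5), "jaccard"), 0)
  expect_equal(marker_list_overlap(a, b, "a"), 103 / 110)
  expect_equal(marker_list_overlap(a, b, "b"), 1)
  expect_equal(marker_list_overlap(a, b, "jaccard"), 103 / 110)
  expect_true(is.na(marker_list_overlap(character(0), a, "a")))
})
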