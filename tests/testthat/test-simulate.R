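test_that("identical effects in both modalities give matching profiles", {
  prof <- tiny_profiles()
  eff <- neutral_effect(prof)
  sim <- simulate_paired_dataset(
    n_donors = 1,
    composition = matrix(rep(0.25, 4), 1,
                         dimnames = list("donor1", prof$types)),
    profiles = prof, effects = list(cell = eff, nucleus = eff),
    n_barcodes = 2000, seed = 5)
  bc <- sim$barcodes
  # per-type per-gene mean counts agree within 3 standard errors
  n_bad <- 0; n_tot <- 0
  for (tt in prof$types) {
    mc <- sim$samples$donor1_cell[, bc$barcode[bc$sample_id ==
      "donor1_cell" & bc$true_type == tt], drop = FALSE]
    mn <- sim$samples$donor1_nucleus[, bc$barcode[bc$sample_id ==
      "donor1_nucleus" & bc$true_type == tt], drop = FALSE]
    se <- sqrt(apply(as.matrix(mc), 1, var) / ncol(mc) +
                 apply(as.matrix(mn), 1, var) / ncol(mn))
    z <- abs(Matrix::rowMeans(mc) - Matrix::rowMeans(mn)) / pmax(se, 1e-9)
    n_bad <- n_bad + sum(z > 3)
    n_tot <- n_tot + length(z)
  }
  expect_lt(n_bad / n_tot, 0.02)
})

test_that("doublet fraction hits its rate and counts are conserved", {
  prof <- tiny_profiles()
  eff <- neutral_effect(prof, doublets = 0.1)
  sim <- simulate_paired_dataset(
    n_donors = 1,
    composition = matrix(rep(0.25, 4), 1,
                         dimnames = list("d1", prof$types)),
    profiles = prof, effects = list(cell = eff, nucleus = eff),
    n_barcodes = 1000, seed = 9)
  bc <- sim$barcodes[sim$barcodes$sample_id == "d1_cell", ]
  n_dbl <- sum(bc$is_doublet)
  bounds <- stats::qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(n_dbl, bounds[1])
  expect_lte(n_dbl, bounds[2])

  m <- sim$samples$d1_cell
  for (i in which(bc$is_doublet)) {
    expect_identical(
      as.numeric(m[, bc$barcode[i]]),
      as.numeric(m[, bc$parent1[i]] + m[, bc$parent2[i]]))
  }
  expect_true(all(bc$parent1[bc$is_doublet] != bc$parent2[bc$is_doublet]))
})

test_that("modality mito/ribo fraction targets are met within 20%", {
  sim <- simulate_paired_dataset(n_donors = 1, n_barcodes = 2000,
                                 seed = 21)
  effs <- default_modality_effects()
  for (mod in c("cell", "nucleus")) {
    m <- sim$samples[[paste0("donor1_", mod)]]
    met <- compute_barcode_metrics(m, mito_genes_by_prefix(rownames(m)),
                                   ribo_genes_by_prefix(rownames(m)))
    t_mito <- effs[[mod]]$mito_fraction_target
    t_ribo <- effs[[mod]]$ribo_fraction_target
    expect_lt(abs(stats::median(met$mito_fraction) - t_mito) / t_mito, 0.2)
    expect_lt(abs(stats::median(met$ribo_fraction) - t_ribo) / t_ribo, 0.2)
  }
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_paired_dataset(n_donors = 2, n_barcodes = 120, seed = 77)
  b <- simulate_paired_dataset(n_donors = 2, n_barcodes = 120, seed = 77)
  expect_identical(lapply(a$samples, as.matrix),
                   lapply(b$samples, as.matrix))
  expect_identical(a$barcodes, b$barcodes)
  c_ <- simulate_paired_dataset(n_donors = 2, n_barcodes = 120, seed = 78)
  expect_false(identical(as.matrix(a$samples[[1]]),
                         as.matrix(c_$samples[[1]])))
})

test_that("higher nuclear detection bias raises the UMI>=3 rate", {
  prof <- tiny_profiles()
  eff_cell <- neutral_effect(prof, libsize_log_mean = 6.5)
  eff_nuc <- neutral_effect(prof, libsize_log_mean = 6.5)
  eff_nuc$detection_bias[["nuclear"]] <- 2.5
  sim <- simulate_paired_dataset(
    n_donors = 1,
    composition = matrix(rep(0.25, 4), 1,
                         dimnames = list("d1", prof$types)),
    profiles = prof, effects = list(cell = eff_cell, nucleus = eff_nuc),
    n_barcodes = 5000, seed = 13)
  g <- sim$gene_classes$gene[sim$gene_classes$class == "nuclear"][1]
  r_cell <- detection_rate(sim$samples$d1_cell, g)
  n_nuc <- ncol(sim$samples$d1_nucleus)
  x_nuc <- sum(sim$samples$d1_nucleus[g, ] >= 3)
  p <- stats::binom.test(x_nuc, n_nuc, p = max(r_cell, 1e-12),
                         alternative = "greater")$p.value
  expect_lt(p, 1e-4)
})

test_that("invalid generator inputs are rejected", {
  prof <- tiny_profiles()
  bad <- matrix(c(0.5, 0.2, 0.2, 0.2), 1,
                dimnames = list("d1", prof$types))
  expect_error(simulate_paired_dataset(
    n_donors = 1, composition = bad, profiles = prof,
    effects = list(cell = neutral_effect(prof),
                   nucleus = neutral_effect(prof)),
    n_barcodes = 50, seed = 1), "sum to 1")
  expect_error(simulate_paired_dataset(n_donors = 1, n_barcodes = 3,
                                       seed = 1),
               "number of cell types")
  expect_error(modality_effect(doublet_rate = 1.4), "proportions")
  expect_error(modality_effect(detection_bias = c(canonical = -1,
                                                  nuclear = 1,
                                                  malat1 = 1)),
               "positive")
})

test_that("identity confusion reproduces the truth labels exactly", {
  sim <- shared_sim()
  singlets <- sim$barcodes[!sim$barcodes$is_doublet, ]
  ann <- simulate_annotation_methods(singlets,
                                     confusion = list(m1 = NULL, m2 = NULL),
                                     score_model = NULL, seed = 2)
  expect_identical(ann$labels$m1, singlets$true_type)
  expect_identical(ann$labels$m2, singlets$true_type)
  for (tt in unique(singlets$true_type)) {
    expect_equal(asymmetric_overlap(ann$labels$m1, ann$labels$m2, tt), 100)
  }
})

test_that("a planted 20% relabel shows up as ~80% directed overlap", {
  truth <- data.frame(barcode = paste0("b", 1:1500),
                      true_type = rep(c("X", "Y", "Z"), each = 500),
                      is_doublet = FALSE, parent1 = NA_character_,
                      stringsAsFactors = FALSE)
  cm <- diag(3); dimnames(cm) <- list(c("X", "Y", "Z"), c("X", "Y", "Z"))
  cmB <- cm; cmB["X", ] <- c(0.8, 0.2, 0)
  ann <- simulate_annotation_methods(truth,
                                     confusion = list(A = NULL, B = cmB),
                                     score_model = NULL, seed = 3)
  ov <- asymmetric_overlap(ann$labels$A, ann$labels$B, "X")
  bounds <- stats::qbinom(c(0.005, 0.995), 500, 0.8) / 500 * 100
  expect_gte(ov, bounds[1])
  expect_lte(ov, bounds[2])
})

test_that("independent uniform errors match the analytic Jaccard", {
  k <- 4
  types <- c("X", paste0("T", 1:(k - 1)))
  n_per <- 12500
  truth <- data.frame(barcode = paste0("b", seq_len(k * n_per)),
                      true_type = rep(types, each = n_per),
                      is_doublet = FALSE, parent1 = NA_character_,
                      stringsAsFactors = FALSE)
  eps <- 0.1
  cm <- matrix(eps / k, k, k, dimnames = list(types, types))
  diag(cm) <- 1 - eps + eps / k
  ann <- simulate_annotation_methods(truth,
                                     confusion = list(A = cm, B = cm),
                                     score_model = NULL, seed = 8)
  p_keep <- 1 - eps + eps / k   # true X labeled X
  q <- eps / k                  # true non-X labeled X
  expected <- (n_per * p_keep^2 + (k - 1) * n_per * q^2) /
    (n_per * (2 * p_keep - p_keep^2) +
       (k - 1) * n_per * (2 * q - q^2))
  got <- jaccard_per_type(ann$labels$A, ann$labels$B, "X")
  expect_lt(abs(got - expected), 0.01)
})

test_that("scores are lower on mislabeled barcodes", {
  truth <- data.frame(barcode = paste0("b", 1:4000),
                      true_type = rep(c("X", "Y"), each = 2000),
                      is_doublet = FALSE, parent1 = NA_character_,
                      stringsAsFactors = FALSE)
  cm <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE,
               dimnames = list(c("X", "Y"), c("X", "Y")))
  ann <- simulate_annotation_methods(truth, confusion = list(A = cm),
                                     seed = 4)
  ok <- ann$labels$A == truth$true_type
  expect_true(all(ann$scores$A >= 0 & ann$scores$A <= 1))
  expect_gt(mean(ann$scores$A[ok]), mean(ann$scores$A[!ok]))
})
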