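#!/usr/bin/env Rscript
# Stage 4: UMI >= 3 gene-detection comparison between modalities, overall
# and per cell type, under both the any-barcode and the 10%-prevalence
# rules.

suppressPackageStartupMessages(library(scnpair))
simdir <- "results/sim"
qcdir <- "results/qc/filtered"
out <- "results/detection"

truth <- read_table_file(file.path(simdir, "barcode_truth.tsv"))
meta <- read_table_file(file.path(simdir, "sample_meta.tsv"))
load_modality <- function(mod) {
  sids <- meta$sample_id[meta$modality == mod]
  ms <- lapply(sids, function(sid) {
    read_mtx_sample(sample_spec(sid, "x", mod,
                                file.path(qcdir, sid, "matrix.mtx"),
                                file.path(qcdir, sid, "features.tsv"),
                                file.path(qcdir, sid, "barcodes.tsv")))
  })
  genes <- Reduce(intersect, lapply(ms, rownames))
  do.call(cbind, lapply(ms, function(m) m[genes, , drop = FALSE]))
}
m_cell <- load_modality("cell")
m_nuc <- load_modality("nucleus")
genes <- intersect(rownames(m_cell), rownames(m_nuc))
m_cell <- m_cell[genes, ]; m_nuc <- m_nuc[genes, ]

rows <- list()
for (prev in c(FALSE, TRUE)) {
  part <- partition_by_modality(m_cell, m_nuc, prevalence = prev)
  rule <- if (prev) "prevalent_10pct" else "any_barcode"
  rows[[rule]] <- data.frame(
    rule = rule, scope = "all", n_union = part$n_union,
    n_both = part$n_both, n_only_cell = part$n_only_a,
    n_only_nucleus = part$n_only_b, pct_both = part$pct_both,
    pct_only_cell = part$pct_only_a, pct_only_nucleus = part$pct_only_b)
  cat(sprintf("%s: %d genes in union, %d%% both, %d%% cell-only, %d%% nucleus-only\n",
              rule, part$n_union, part$pct_both, part$pct_only_a,
              part$pct_only_b))
}
# per cell type under the any-barcode rule
types <- sort(unique(truth$true_type[!truth$is_doublet]))
for (tt in types) {
  bc_c <- intersect(colnames(m_cell),
                    truth$barcode[truth$true_type == tt])
  bc_n <- intersect(colnames(m_nuc),
                    truth$barcode[truth$true_type == tt])
  if (length(bc_c) < 10 || length(bc_n) < 10) next
  part <- partition_by_modality(m_cell[, bc_c], m_nuc[, bc_n])
  rows[[tt]] <- data.frame(
    rule = "any_barcode", scope = tt, n_union = part$n_union,
    n_both = part$n_both, n_only_cell = part$n_only_a,
    n_only_nucleus = part$n_only_b, pct_both = part$pct_both,
    pct_only_cell = part$pct_only_a, pct_only_nucleus = part$pct_only_b)
}
write_table(do.call(rbind, c(rows, make.row.names = FALSE)),
            file.path(out, "detection_partition.tsv"))

# canonical marker detection rates per modality in their own cell type
canon <- c(beta = "INS", alpha = "GCG", delta = "SST", gamma = "PPY")
dr <- do.call(rbind, lapply(names(canon), function(tt) {
  g <- canon[[tt]]
  bc_c <- intersect(colnames(m_cell),
                    truth$barcode[truth$true_type == tt])
  bc_n <- intersect(colnames(m_nuc),
                    truth$barcode[truth$true_type == tt])
  data.frame(gene = g, cell_type = tt,
             rate_cell = detection_rate(m_cell, g, bc_c),
             rate_nucleus = detection_rate(m_nuc, g, bc_n))
}))
write_table(dr, file.path(out, "canonical_detection_rates.tsv"))
cat("Canonical marker detection (cell vs nucleus):\n")
print(dr, row.names = FALSE)
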