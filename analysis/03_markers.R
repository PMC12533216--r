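#!/usr/bin/env Rscript
# Stage 3: log-normalize the QC-passed matrices, run the strict cell-type
# marker test (log2FC > 1, detected in >= 50% of the type, FDR < 0.05)
# per modality, and compare the resulting marker lists across modalities.

suppressPackageStartupMessages(library(scnpair))
simdir <- "results/sim"
qcdir <- "results/qc/filtered"
out <- "results/markers"

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

marker_sets <- list()
for (mod in c("cell", "nucleus")) {
  m <- load_modality(mod)
  grp <- truth$true_type[match(colnames(m), truth$barcode)]
  ok <- grp %in% names(which(table(grp) >= 10))
  res <- find_markers(log_normalize(m[, ok]), grp[ok],
                      marker_params(min_pct = 0.50))
  write_table(res, file.path(out, paste0("markers_", mod, ".tsv")))
  marker_sets[[mod]] <- split(res$gene[res$is_marker],
                              res$group[res$is_marker])
  cat(mod, ":", sum(res$is_marker), "strict markers across",
      length(unique(res$group)), "cell types\n")
}

shared <- intersect(names(marker_sets$cell), names(marker_sets$nucleus))
ovl <- do.call(rbind, lapply(shared, function(tt) {
  data.frame(cell_type = tt,
             n_cell = length(marker_sets$cell[[tt]]),
             n_nucleus = length(marker_sets$nucleus[[tt]]),
             jaccard = marker_list_overlap(marker_sets$cell[[tt]],
                                           marker_sets$nucleus[[tt]],
                                           "jaccard"),
             over_cell = marker_list_overlap(marker_sets$cell[[tt]],
                                             marker_sets$nucleus[[tt]],
                                             "a"))
}))
write_table(ovl, file.path(out, "marker_overlap.tsv"))
cat("Cross-modality marker overlap (Jaccard), median:",
    sprintf("%.2f", median(ovl$jaccard, na.rm = TRUE)), "\n")
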