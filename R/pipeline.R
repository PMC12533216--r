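#' Assemble a full-run configuration
#'
#' @param qc A [qc_thresholds()].
#' @param marker_loose,marker_strict [marker_params()] for the loose
#'   cluster-marker pass (25% detection) and the strict cell-type pass
#'   (50%).
#' @param detection A [detection_params()].
#' @param harmonization_map Named raw -> harmonized label vector.
#' @param bootstrap_resamples Bootstrap resamples for paired stats (>= 1).
#' @param rng_seed Integer seed driving every stochastic step.
#' @param output_dir Directory for stage tables, or NULL to skip writing.
#' @param n_donors,n_barcodes Synthetic design size when simulating.
#' @return A `run_config` list.
#' @export
run_config <- function(qc = qc_thresholds(),
                       marker_loose = marker_params(min_pct = 0.25),
                       marker_strict = marker_params(min_pct = 0.50),
                       detection = detection_params(),
                       harmonization_map = default_harmonization_map(),
                       bootstrap_resamples = 10000L,
                       rng_seed = 1L,
                       output_dir = NULL,
                       n_donors = 4L,
                       n_barcodes = 500L) {
  stopifnot(bootstrap_resamples >= 1L)
  structure(list(qc = qc, marker_loose = marker_loose,
                 marker_strict = marker_strict, detection = detection,
                 harmonization_map = harmonization_map,
                 bootstrap_resamples = as.integer(bootstrap_resamples),
                 rng_seed = as.integer(rng_seed),
                 output_dir = output_dir, n_donors = as.integer(n_donors),
                 n_barcodes = n_barcodes),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Recognized top-level keys: `qc_thresholds`, `marker_loose`,
#' `marker_strict`, `detection`, `harmonization_map`,
#' `bootstrap_resamples`, `rng_seed`, `output_dir`, `n_donors`,
#' `n_barcodes`; missing keys fall back to [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$qc_thresholds)) {
    args$qc <- do.call(qc_thresholds, y$qc_thresholds)
  }
  if (!is.null(y$marker_loose)) {
    args$marker_loose <- do.call(marker_params, y$marker_loose)
  }
  if (!is.null(y$marker_strict)) {
    args$marker_strict <- do.call(marker_params, y$marker_strict)
  }
  if (!is.null(y$detection)) {
    args$detection <- do.call(detection_params, y$detection)
  }
  if (!is.null(y$harmonization_map)) {
    args$harmonization_map <- unlist(y$harmonization_map)
  }
  for (k in c("bootstrap_resamples", "rng_seed", "output_dir", "n_donors",
              "n_barcodes")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

#' Run the full paired-modality comparison pipeline on synthetic data
#'
#' Stages: simulate paired samples -> per-sample QC cascade -> pooled
#' per-modality matrices -> log-normalization and strict cell-type markers
#' per modality -> cross-modality marker-list overlap -> UMI-threshold
#' detection partition -> multi-method annotation concordance -> donor-level
#' paired statistics on the QC metrics (mito/ribo fraction, features and
#' counts per barcode, complexity) plus per-sample scalars (ambient,
#' doublet, intronic fractions). Tables are written under
#' `config$output_dir` when set; per-stage barcode/gene counts are recorded
#' in the returned `log`.
#'
#' @param config A [run_config()].
#' @param sim Optional pre-built [simulate_paired_dataset()] result; by
#'   default one is generated from the config's seed and sizes.
#' @return List: `sim`, `qc` (records, summaries, filtered matrices),
#'   `markers` (per modality), `marker_overlap`, `detection`,
#'   `concordance`, `paired` (adjusted PairedStatResult table), `log`.
#' @export
run_pipeline <- function(config = run_config(), sim = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(sim)) {
    sim <- simulate_paired_dataset(n_donors = config$n_donors,
                                   n_barcodes = config$n_barcodes,
                                   seed = config$rng_seed)
  }
  if (!any(duplicated(sim$sample_meta$donor_id))) {
    stop("paired statistics need at least one donor with both modalities")
  }
  logs <- list()

  ## --- QC per sample -------------------------------------------------
  records <- list(); summaries <- list(); filtered <- list()
  for (sid in names(sim$samples)) {
    m <- sim$samples[[sid]]
    bc <- sim$barcodes[sim$barcodes$sample_id == sid, ]
    dbl <- stats::setNames(bc$is_doublet, bc$barcode)
    fl <- apply_filters(m, dbl, config$qc)
    rec <- fl$records
    rec$sample_id <- sid
    rec$donor_id <- bc$donor_id[match(rec$barcode, bc$barcode)]
    rec$modality <- bc$modality[match(rec$barcode, bc$barcode)]
    records[[sid]] <- rec
    meta <- sim$sample_meta[sim$sample_meta$sample_id == sid, ]
    summaries[[sid]] <- cbind(sample_id = sid, summarize_sample(rec, meta))
    filtered[[sid]] <- fl$matrix
    logs[[paste0("qc_", sid)]] <- fl$stage_counts
  }
  records <- do.call(rbind, c(records, make.row.names = FALSE))
  summaries <- do.call(rbind, c(summaries, make.row.names = FALSE))

  ## --- pool per modality (shared gene universe: union of survivors) ---
  pool <- function(mod) {
    ms <- filtered[sim$sample_meta$sample_id[
      sim$sample_meta$modality == mod]]
    genes <- sort(unique(unlist(lapply(ms, rownames))))
    cols <- lapply(ms, function(m) {
      full <- Matrix::Matrix(0, length(genes), ncol(m), sparse = TRUE,
                             dimnames = list(genes, colnames(m)))
      full[rownames(m), ] <- m
      full
    })
    do.call(cbind, cols)
  }
  m_cell <- pool("cell")
  m_nuc <- pool("nucleus")
  shared <- intersect(rownames(m_cell), rownames(m_nuc))
  logs$pooled <- c(cells = ncol(m_cell), nuclei = ncol(m_nuc),
                   shared_genes = length(shared))

  ## --- markers per modality (truth types as the annotation) ----------
  kept_types <- function(m) {
    tt <- sim$barcodes$true_type[match(colnames(m), sim$barcodes$barcode)]
    stats::setNames(tt, colnames(m))
  }
  markers <- list()
  for (mod in c("cell", "nucleus")) {
    m <- if (mod == "cell") m_cell else m_nuc
    norm <- log_normalize(m, config$marker_strict$scale_factor)
    grp <- kept_types(m)
    keep <- names(grp)[grp %in% names(which(table(grp) >= 3))]
    markers[[mod]] <- find_markers(norm[, keep, drop = FALSE], grp[keep],
                                   config$marker_strict)
  }
  mk <- function(mod) {
    tab <- markers[[mod]]
    split(tab$gene[tab$is_marker], tab$group[tab$is_marker])
  }
  mk_cell <- mk("cell"); mk_nuc <- mk("nucleus")
  marker_overlap <- do.call(rbind, lapply(
    intersect(names(mk_cell), names(mk_nuc)), function(tt) {
      data.frame(cell_type = tt,
                 n_cell = length(mk_cell[[tt]]),
                 n_nucleus = length(mk_nuc[[tt]]),
                 jaccard = marker_list_overlap(mk_cell[[tt]], mk_nuc[[tt]],
                                               "jaccard"),
                 over_a = marker_list_overlap(mk_cell[[tt]], mk_nuc[[tt]],
                                              "a"),
                 over_b = marker_list_overlap(mk_cell[[tt]], mk_nuc[[tt]],
                                              "b"),
                 stringsAsFactors = FALSE)
    }))

  ## --- detection ------------------------------------------------------
  part_any <- partition_by_modality(m_cell[shared, , drop = FALSE],
                                    m_nuc[shared, , drop = FALSE],
                                    config$detection)
  part_prev <- partition_by_modality(m_cell[shared, , drop = FALSE],
                                     m_nuc[shared, , drop = FALSE],
                                     config$detection, prevalence = TRUE)

  ## --- annotation concordance ----------------------------------------
  kept_bc <- sim$barcodes[sim$barcodes$barcode %in%
                            c(colnames(m_cell), colnames(m_nuc)), ]
  types <- sort(unique(kept_bc$true_type[!kept_bc$is_doublet]))
  conf <- diag(length(types)) * 0.9 + (1 - 0.9) / length(types)
  dimnames(conf) <- list(types, types)
  ann <- simulate_annotation_methods(
    kept_bc, confusion = list(manual = NULL, refA = conf, refB = conf),
    seed = config$rng_seed + 1L)
  harm <- harmonize(ann$labels, config$harmonization_map,
                    passthrough = unique(unlist(ann$labels[-1L])))
  conc <- concordance_report(harm$labels, kept_bc, ann$scores)

  ## --- paired donor-level statistics ----------------------------------
  kept_rec <- records[records$kept, ]
  tests <- list()
  for (met in c("mito_fraction", "ribo_fraction", "n_features",
                "n_counts", "complexity")) {
    pr <- aggregate_per_donor(kept_rec, met)
    tests[[met]] <- paired_modality_test(
      pr, metric = met, resamples = config$bootstrap_resamples,
      seed = config$rng_seed, family = "qc")
  }
  for (met in c("ambient_fraction", "doublet_fraction",
                "intronic_fraction")) {
    pr <- aggregate_per_donor(sim$sample_meta, met)
    tests[[met]] <- paired_modality_test(
      pr, metric = met, resamples = config$bootstrap_resamples,
      seed = config$rng_seed, family = "sample_qc")
  }
  paired <- family_adjust(do.call(rbind, c(tests,
                                           make.row.names = FALSE)))

  out <- list(sim = sim,
              qc = list(records = records, summaries = summaries,
                        matrices = filtered),
              markers = markers, marker_overlap = marker_overlap,
              detection = list(any_barcode = part_any,
                               prevalent = part_prev),
              concordance = conc, paired = paired, log = logs)

  if (!is.null(config$output_dir)) {
    od <- config$output_dir
    write_table(summaries, file.path(od, "sample_summaries.tsv"))
    write_table(records, file.path(od, "barcode_records.tsv"))
    for (mod in names(markers)) {
      write_table(markers[[mod]],
                  file.path(od, paste0("markers_", mod, ".tsv")))
    }
    write_table(marker_overlap, file.path(od, "marker_overlap.tsv"))
    write_table(part_any$membership, file.path(od, "detection_genes.tsv"))
    write_table(data.frame(
      rule = c("any_barcode", "prevalent_10pct"),
      n_union = c(part_any$n_union, part_prev$n_union),
      n_both = c(part_any$n_both, part_prev$n_both),
      n_only_cell = c(part_any$n_only_a, part_prev$n_only_a),
      n_only_nucleus = c(part_any$n_only_b, part_prev$n_only_b),
      pct_both = c(part_any$pct_both, part_prev$pct_both),
      pct_only_cell = c(part_any$pct_only_a, part_prev$pct_only_a),
      pct_only_nucleus = c(part_any$pct_only_b, part_prev$pct_only_b)),
      file.path(od, "detection_partition.tsv"))
    write_table(conc$overlap, file.path(od, "concordance_overlap.tsv"))
    write_table(conc$jaccard, file.path(od, "concordance_jaccard.tsv"))
    write_table(conc$mean_jaccard,
                file.path(od, "concordance_mean_jaccard.tsv"))
    write_table(conc$weighted_jaccard,
                file.path(od, "concordance_weighted_jaccard.tsv"))
    write_table(paired, file.path(od, "paired_stats.tsv"))
  }
  out
}
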