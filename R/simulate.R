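#' Build cell-type expression profiles for a pancreatic-islet-like universe
#'
#' Constructs a gene universe partitioned into classes (canonical markers,
#' nuclear-enriched markers, mitochondrial, ribosomal, MALAT1, background)
#' and one relative expression-rate vector per cell type. Every type carries
#' the same total mass per class, so class fractions (e.g. the mitochondrial
#' share) are identical across types by construction; within the canonical
#' class, each type's own markers are enriched by a fixed fold over the mean
#' rate of the same gene in all other types.
#'
#' The first four types are the islet endocrine types beta, alpha, delta and
#' gamma, whose first markers are named INS, GCG, SST and PPY so that the
#' ambient "soup" is INS-dominated whenever beta cells dominate.
#'
#' @param n_types Number of cell types (default 10).
#' @param markers_per_type Canonical markers per type (default 15).
#' @param n_nuclear Nuclear-enriched marker genes shared by all types.
#' @param n_mito,n_ribo Mitochondrial / ribosomal gene counts.
#' @param n_genes Total gene universe size (default 2000).
#' @param enrichment_log2 Declared log2 fold enrichment of each type's own
#'   markers over the mean of the other types (default 2, i.e. 4-fold).
#' @param hormone_share Share of a type's own-marker budget carried by its
#'   first marker (the hormone gene for endocrine types). The default 0.85
#'   makes INS the most abundant single transcript in the ambient soup
#'   whenever beta cells dominate the mixture; set to
#'   `1 / markers_per_type` for a flat marker profile.
#' @param class_mass Named masses allotted per type to the canonical,
#'   nuclear, mito, ribo and malat1 classes; background takes the remainder.
#' @return A `cell_type_profiles` list with elements `rates` (genes x types
#'   matrix, columns sum to 1), `classes` (per-gene class factor), `markers`
#'   (list of marker gene ids per type), `types`.
#' @export
islet_profiles <- function(n_types = 10, markers_per_type = 15,
                           n_nuclear = 40, n_mito = 13, n_ribo = 50,
                           n_genes = 2000, enrichment_log2 = 2,
                           hormone_share = 0.85,
                           class_mass = c(canonical = 0.25,
                                          nuclear = 0.04,
                                          mito = 0.034,
                                          ribo = 0.086,
                                          malat1 = 0.02)) {
  stopifnot(n_types >= 2, markers_per_type >= 2)
  endocrine <- c("beta", "alpha", "delta", "gamma")
  extra <- c("acinar", "ductal", "endothelial", "immune", "mesenchymal",
             paste0("type", seq_len(max(0, n_types - 9))))
  types <- c(endocrine, extra)[seq_len(n_types)]
  canon_names <- c("INS", "GCG", "SST", "PPY")

  n_canon <- n_types * markers_per_type
  n_bg <- n_genes - n_canon - n_nuclear - n_mito - n_ribo - 1L
  stopifnot(n_bg >= 2)

  genes <- character(0)
  classes <- character(0)
  markers <- vector("list", n_types)
  names(markers) <- types
  for (i in seq_len(n_types)) {
    ids <- paste0("MK", i, "_", seq_len(markers_per_type))
    if (i <= length(canon_names)) ids[1L] <- canon_names[i]
    markers[[i]] <- ids
    genes <- c(genes, ids)
    classes <- c(classes, rep("canonical", markers_per_type))
  }
  genes <- c(genes,
             paste0("NUC", seq_len(n_nuclear)),
             paste0("MT-", seq_len(n_mito)),
             c(paste0("RPL", seq_len(ceiling(n_ribo / 2))),
               paste0("RPS", seq_len(n_ribo - ceiling(n_ribo / 2)))),
             "MALAT1",
             paste0("BG", seq_len(n_bg)))
  classes <- c(classes, rep("nuclear", n_nuclear), rep("mito", n_mito),
               rep("ribo", n_ribo), "malat1", rep("background", n_bg))
  classes <- factor(classes, levels = c("canonical", "nuclear", "mito",
                                        "ribo", "malat1", "background"))

  fold <- 2^enrichment_log2
  stopifnot(hormone_share > 0, hormone_share < 1)
  # Each type's own-marker budget B is equal, and every marker's off-type
  # rate is its own rate / fold, so the canonical block mass
  # B + (n_types-1) * B / fold is identical in every type.
  budget <- class_mass[["canonical"]] / (1 + (n_types - 1) / fold)
  own_rate <- c(hormone_share * budget,
                rep((1 - hormone_share) * budget / (markers_per_type - 1),
                    markers_per_type - 1L))

  rates <- matrix(0, nrow = n_genes, ncol = n_types,
                  dimnames = list(genes, types))
  for (i in seq_len(n_types)) {
    for (j in seq_len(n_types)) {
      rates[markers[[j]], i] <- if (i == j) own_rate else own_rate / fold
    }
  }
  rates[classes == "nuclear", ] <- class_mass[["nuclear"]] / n_nuclear
  rates[classes == "mito", ] <- class_mass[["mito"]] / n_mito
  rates[classes == "ribo", ] <- class_mass[["ribo"]] / n_ribo
  rates[classes == "malat1", ] <- class_mass[["malat1"]]
  bg_mass <- 1 - sum(class_mass)
  stopifnot(bg_mass > 0)
  rates[classes == "background", ] <- bg_mass / n_bg

  obj <- structure(
    list(rates = rates, classes = classes, markers = markers, types = types,
         enrichment_log2 = enrichment_log2),
    class = "cell_type_profiles")
  validate_profiles(obj)
  obj
}

validate_profiles <- function(p) {
  cs <- colSums(p$rates)
  if (any(abs(cs - 1) > 1e-9)) stop("profile rates must sum to 1 per type")
  fold <- 2^p$enrichment_log2
  for (t in names(p$markers)) {
    own <- p$rates[p$markers[[t]], t, drop = FALSE]
    other <- rowMeans(p$rates[p$markers[[t]],
                              setdiff(colnames(p$rates), t), drop = FALSE])
    if (any(own / other < fold - 1e-9)) {
      stop("declared markers of ", t, " are under-enriched")
    }
  }
  invisible(p)
}

#' Describe per-modality detection and composition effects
#'
#' @param detection_bias Named per-class multiplicative detection factors for
#'   the `canonical`, `nuclear` and `malat1` classes (background is 1).
#' @param mito_fraction_target,ribo_fraction_target Expected per-barcode
#'   count fractions on the mito / ribo gene classes in this modality.
#' @param ambient_fraction Per-sample ambient ("soup") fraction, recycled or
#'   one value per donor.
#' @param doublet_rate Per-sample doublet rate, recycled likewise.
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size
#'   parameters (natural log of total UMI per barcode).
#' @param intronic_fraction Per-sample intronic read fraction emitted as
#'   metadata only.
#' @return A `modality_effect` list.
#' @export
modality_effect <- function(detection_bias = c(canonical = 1, nuclear = 1,
                                               malat1 = 1),
                            mito_fraction_target = 0.034,
                            ribo_fraction_target = 0.086,
                            ambient_fraction = 0.02,
                            doublet_rate = 0.08,
                            libsize_log_mean = 9.2,
                            libsize_log_sd = 0.35,
                            intronic_fraction = 0.19) {
  props <- c(mito_fraction_target, ribo_fraction_target,
             ambient_fraction, doublet_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (any(!is.finite(detection_bias)) || any(detection_bias <= 0)) {
    stop("detection_bias factors must be finite and positive")
  }
  structure(list(detection_bias = detection_bias,
                 mito_fraction_target = mito_fraction_target,
                 ribo_fraction_target = ribo_fraction_target,
                 ambient_fraction = ambient_fraction,
                 doublet_rate = doublet_rate,
                 libsize_log_mean = libsize_log_mean,
                 libsize_log_sd = libsize_log_sd,
                 intronic_fraction = intronic_fraction),
            class = "modality_effect")
}

#' Default study-design modality effects
#'
#' Cells: mito/ribo fractions ~3.4%/8.6%, ambient 1-2.4%, doublets 3-11%,
#' intronic ~19%. Nuclei: near-zero mito/ribo, ambient 1.9-7.4%, doublets
#' 6.6-14%, intronic ~54%, canonical markers depleted and nuclear-enriched
#' markers elevated, smaller libraries.
#'
#' @return Named list with `cell` and `nucleus` [modality_effect()]s.
#' @export
default_modality_effects <- function() {
  list(
    cell = modality_effect(
      detection_bias = c(canonical = 1, nuclear = 1, malat1 = 1),
      mito_fraction_target = 0.034, ribo_fraction_target = 0.086,
      ambient_fraction = c(0.021, 0.024, 0.013, 0.019),
      doublet_rate = c(0.11, 0.091, 0.032, 0.10),
      libsize_log_mean = 9.2, libsize_log_sd = 0.35,
      intronic_fraction = c(0.19, 0.22, 0.20, 0.14)),
    nucleus = modality_effect(
      detection_bias = c(canonical = 0.35, nuclear = 2.5, malat1 = 2),
      mito_fraction_target = 0.0005, ribo_fraction_target = 0.002,
      ambient_fraction = c(0.036, 0.074, 0.019, 0.027),
      doublet_rate = c(0.076, 0.14, 0.077, 0.066),
      libsize_log_mean = 8.4, libsize_log_sd = 0.30,
      intronic_fraction = c(0.56, 0.55, 0.53, 0.51)))
}

#' Default donor cell-type compositions
#'
#' Four fixed islet-like mixtures with beta/alpha dominance varying by donor.
#'
#' @param types Cell-type names (from [islet_profiles()]).
#' @param n_donors Number of donors.
#' @return Matrix donors x types, rows sum to 1.
#' @export
default_composition <- function(types, n_donors = 4) {
  n <- length(types)
  base <- c(0.38, 0.30, 0.04, 0.02, 0.06, 0.07, 0.05, 0.02, 0.06)
  base <- c(base, rep(0.01, max(0, n - 9)))[seq_len(n)]
  base <- base / sum(base)
  shifts <- c(0.9, 1.1, 1.25, 0.8)
  comp <- t(vapply(seq_len(n_donors), function(d) {
    w <- base
    w[1] <- w[1] * shifts[((d - 1) %% 4) + 1]       # beta share varies
    w[2] <- w[2] * shifts[((d) %% 4) + 1]           # alpha share varies
    w / sum(w)
  }, numeric(n)))
  dimnames(comp) <- list(paste0("donor", seq_len(n_donors)), types)
  comp
}

# Resolve the per-gene detection-bias vector for a modality. Mito and ribo
# classes are pinned so their expected count fractions equal the targets
# exactly (class masses are identical across types); the remaining classes
# get their raw factors, rescaled as a block to keep the expected library
# size at its nominal value.
resolve_detection_bias <- function(profiles, effect) {
  cls <- profiles$classes
  mass <- vapply(split(profiles$rates[, 1L], cls), sum, numeric(1))
  t_mito <- effect$mito_fraction_target
  t_ribo <- effect$ribo_fraction_target
  raw <- rep(1, length(cls))
  for (k in c("canonical", "nuclear", "malat1")) {
    raw[cls == k] <- effect$detection_bias[[k]]
  }
  block <- !(cls %in% c("mito", "ribo"))
  block_mass <- sum(profiles$rates[block, 1L] * raw[block])
  lambda <- (1 - t_mito - t_ribo) / block_mass
  bias <- raw * lambda
  bias[cls == "mito"] <- t_mito / mass[["mito"]]
  bias[cls == "ribo"] <- t_ribo / mass[["ribo"]]
  names(bias) <- rownames(profiles$rates)
  bias
}

#' Simulate a donor-paired cell/nucleus UMI dataset with known truth
#'
#' For each donor x modality sample, singlet barcodes draw a cell type from
#' the donor's composition, a log-normal library size, and Poisson counts
#' with per-gene mean
#' `libsize * ((1 - a) * profile(type) + a * soup) * detection_bias`,
#' where the soup is the composition-weighted average of the sample's type
#' profiles. Doublet barcodes are the elementwise sum of two distinct
#' singlet barcodes of the same sample (the parents), so doublet totals
#' conserve parent totals exactly.
#'
#' @param n_donors Number of donors (default 4).
#' @param composition Donor x type proportion matrix (rows sum to 1).
#' @param profiles A [islet_profiles()] object.
#' @param effects Named list with `cell` and `nucleus` [modality_effect()]s.
#' @param n_barcodes Barcodes per sample (recycled over samples).
#' @param seed Integer seed; all randomness flows through one RNG stream.
#' @return List with `samples` (named list of sparse genes x barcodes
#'   matrices), `barcodes` (per-barcode truth data.frame: barcode, sample_id,
#'   donor_id, modality, true_type, is_doublet, parent1, parent2),
#'   `sample_meta` (per-sample realized ambient/doublet/intronic fractions
#'   and soup INS share), `gene_classes` (per-gene class data.frame), and
#'   `bias` (per-modality detection-bias vectors).
#' @export
simulate_paired_dataset <- function(n_donors = 4,
                                    composition = NULL,
                                    profiles = islet_profiles(),
                                    effects = default_modality_effects(),
                                    n_barcodes = 500,
                                    seed = 1) {
  if (is.null(composition)) {
    composition <- default_composition(profiles$types, n_donors)
  }
  if (any(abs(rowSums(composition) - 1) > 1e-6)) {
    stop("composition rows must sum to 1")
  }
  stopifnot(ncol(composition) == length(profiles$types),
            nrow(composition) == n_donors)
  n_barcodes <- rep_len(n_barcodes, n_donors * 2L)
  if (any(n_barcodes < length(profiles$types))) {
    stop("n_barcodes must be at least the number of cell types")
  }

  set.seed(seed)
  genes <- rownames(profiles$rates)
  ins_idx <- match("INS", genes)
  samples <- list()
  bc_rows <- list()
  meta_rows <- list()
  bias <- lapply(effects, function(e) resolve_detection_bias(profiles, e))

  si <- 0L
  for (d in seq_len(n_donors)) {
    donor <- rownames(composition)[d]
    for (mod in c("cell", "nucleus")) {
      si <- si + 1L
      eff <- effects[[mod]]
      nb <- n_barcodes[si]
      amb <- rep_len(eff$ambient_fraction, n_donors)[d]
      drate <- rep_len(eff$doublet_rate, n_donors)[d]
      intr <- rep_len(eff$intronic_fraction, n_donors)[d]
      sid <- paste0(donor, "_", mod)

      comp <- composition[d, ]
      soup <- as.numeric(profiles$rates %*% comp)
      types <- sample(profiles$types, nb, replace = TRUE, prob = comp)
      libsize <- stats::rlnorm(nb, eff$libsize_log_mean, eff$libsize_log_sd)
      mix <- (1 - amb) * profiles$rates[, types, drop = FALSE] + amb * soup
      mu <- mix * bias[[mod]]
      mu <- sweep(mu, 2L, libsize, `*`)
      counts <- matrix(stats::rpois(length(mu), as.numeric(mu)),
                       nrow = nrow(mu))

      n_dbl <- stats::rbinom(1L, nb, drate)
      n_dbl <- min(n_dbl, nb - 2L)
      is_dbl <- rep(FALSE, nb)
      parent1 <- parent2 <- rep(NA_character_, nb)
      bc_names <- sprintf("%s_BC%04d", sid, seq_len(nb))
      if (n_dbl > 0) {
        dbl_idx <- sample(nb, n_dbl)
        is_dbl[dbl_idx] <- TRUE
        singlets <- which(!is_dbl)
        for (i in dbl_idx) {
          par <- sample(singlets, 2L)
          counts[, i] <- counts[, par[1L]] + counts[, par[2L]]
          parent1[i] <- bc_names[par[1L]]
          parent2[i] <- bc_names[par[2L]]
          types[i] <- paste(sort(c(types[par[1L]], types[par[2L]])),
                            collapse = "+")
        }
      }
      dimnames(counts) <- list(genes, bc_names)
      samples[[sid]] <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix")
      bc_rows[[sid]] <- data.frame(
        barcode = bc_names, sample_id = sid, donor_id = donor,
        modality = mod, true_type = types, is_doublet = is_dbl,
        parent1 = parent1, parent2 = parent2, stringsAsFactors = FALSE)
      meta_rows[[sid]] <- data.frame(
        sample_id = sid, donor_id = donor, modality = mod,
        n_barcodes = nb, ambient_fraction = amb,
        doublet_fraction = mean(is_dbl),
        intronic_fraction = intr,
        soup_ins_share = soup[ins_idx] / sum(soup),
        stringsAsFactors = FALSE)
    }
  }

  list(samples = samples,
       barcodes = do.call(rbind, c(bc_rows, make.row.names = FALSE)),
       sample_meta = do.call(rbind, c(meta_rows, make.row.names = FALSE)),
       gene_classes = data.frame(gene = genes,
                                 class = as.character(profiles$classes),
                                 stringsAsFactors = FALSE),
       bias = bias)
}

#' Simulate multi-method annotation labels and confidence scores
#'
#' Each "method" relabels every singlet barcode by drawing from the confusion
#' row of its true type; doublets inherit a draw from their first parent's
#' type. Prediction/mapping-style scores are Beta-distributed in `[0, 1]`,
#' lower on mislabeled barcodes.
#'
#' @param truth Barcode truth data.frame from [simulate_paired_dataset()]
#'   (needs `barcode`, `true_type`, `is_doublet`, `parent1`).
#' @param confusion Named list per method: a types x types row-stochastic
#'   confusion matrix (rows = true type, columns = assigned label). A method
#'   may be given `NULL` for identity labeling.
#' @param score_model List with `correct` and `wrong` Beta shape pairs
#'   `c(shape1, shape2)`; `NULL` disables scores.
#' @param seed Integer seed.
#' @return List with `labels` (data.frame barcode + one column per method)
#'   and `scores` (same shape, or NULL).
#' @export
simulate_annotation_methods <- function(truth, confusion,
                                        score_model = list(
                                          correct = c(8, 1.2),
                                          wrong = c(2.5, 2.5)),
                                        seed = 1) {
  set.seed(seed)
  base_type <- truth$true_type
  dbl <- which(truth$is_doublet)
  if (length(dbl)) {
    base_type[dbl] <- truth$true_type[match(truth$parent1[dbl],
                                            truth$barcode)]
  }
  labels <- data.frame(barcode = truth$barcode, stringsAsFactors = FALSE)
  scores <- data.frame(barcode = truth$barcode, stringsAsFactors = FALSE)
  for (meth in names(confusion)) {
    cm <- confusion[[meth]]
    if (is.null(cm)) {
      lab <- base_type
    } else {
      if (any(abs(rowSums(cm) - 1) > 1e-8)) {
        stop("confusion rows for ", meth, " must sum to 1")
      }
      lab <- vapply(base_type, function(tt) {
        if (!tt %in% rownames(cm)) return(tt)
        sample(colnames(cm), 1L, prob = cm[tt, ])
      }, character(1), USE.NAMES = FALSE)
    }
    labels[[meth]] <- lab
    if (!is.null(score_model)) {
      ok <- lab == base_type
      s <- numeric(length(lab))
      s[ok] <- stats::rbeta(sum(ok), score_model$correct[1L],
                            score_model$correct[2L])
      s[!ok] <- stats::rbeta(sum(!ok), score_model$wrong[1L],
                             score_model$wrong[2L])
      scores[[meth]] <- s
    }
  }
  list(labels = labels,
       scores = if (is.null(score_model)) NULL else scores)
}
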