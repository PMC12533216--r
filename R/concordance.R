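#' Default cell-type label harmonization map
#'
#' Maps method-specific labels onto a shared vocabulary before comparing
#' annotations: ductal variants collapse to ductal, gamma+epsilon to gamma,
#' mast/macrophage to immune, stellate/Schwann variants to mesenchymal;
#' alpha and beta stay distinct (alpha+beta is its own category).
#'
#' @return Named character vector raw -> harmonized.
#' @export
default_harmonization_map <- function() {
  c("ductal" = "ductal", "MUC5B+ ductal" = "ductal",
    "gamma" = "gamma", "gamma+epsilon" = "gamma",
    "mast" = "immune", "macrophage" = "immune", "immune" = "immune",
    "activated stellate" = "mesenchymal",
    "quiescent stellate" = "mesenchymal",
    "quiescent_stellate" = "mesenchymal",
    "activated_stellate" = "mesenchymal",
    "Schwann" = "mesenchymal", "stellate" = "mesenchymal",
    "mesenchymal" = "mesenchymal",
    "alpha" = "alpha", "beta" = "beta", "alpha+beta" = "alpha+beta",
    "delta" = "delta", "acinar" = "acinar", "endothelial" = "endothelial",
    "cycling" = "cycling")
}

#' Harmonize annotation labels across methods
#'
#' @param labels Data.frame with a `barcode` column and one label column per
#'   method.
#' @param map Either a named character vector raw -> harmonized applied to
#'   every method, or a list of such vectors keyed by method.
#' @param passthrough Labels allowed to pass unmapped (kept verbatim).
#'   Any other unmapped observed label is an error listing the offenders.
#' @return List with `labels` (rewritten data.frame) and `audit`
#'   (original -> harmonized count table).
#' @export
harmonize <- function(labels, map = default_harmonization_map(),
                      passthrough = character(0)) {
  stopifnot("barcode" %in% names(labels))
  methods_cols <- setdiff(names(labels), "barcode")
  out <- labels
  audits <- list()
  for (meth in methods_cols) {
    mp <- if (is.list(map)) map[[meth]] else map
    if (is.null(mp)) stop("no harmonization map for method ", meth)
    raw <- labels[[meth]]
    known <- raw %in% names(mp) | raw %in% passthrough | is.na(raw)
    if (!all(known)) {
      stop("unmapped labels for ", meth, ": ",
           paste(sort(unique(raw[!known])), collapse = ", "))
    }
    new <- ifelse(raw %in% names(mp), unname(mp[raw]), raw)
    out[[meth]] <- new
    tab <- as.data.frame(table(original = raw, harmonized = new),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    tab$method <- meth
    audits[[meth]] <- tab
  }
  list(labels = out,
       audit = do.call(rbind, c(audits, make.row.names = FALSE)))
}

#' Asymmetric annotation overlap for one cell type
#'
#' Percentage of barcodes labeled `cell_type` by method A that method B also
#' labels `cell_type`:
#' `100 * |{a = type & b = type}| / |{a = type}|`. Stored at full precision;
#' round only at report time. Barcodes unlabeled (NA) by either method are
#' excluded (pairwise-complete).
#'
#' @param labels_a,labels_b Label vectors over the same barcode universe.
#' @param cell_type The harmonized type to compare.
#' @return Percentage, or NA when method A assigns nobody to the type.
#' @export
asymmetric_overlap <- function(labels_a, labels_b, cell_type) {
  stopifnot(length(labels_a) == length(labels_b))
  ok <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[ok]; b <- labels_b[ok]
  denom <- sum(a == cell_type)
  if (denom == 0L) return(NA_real_)
  100 * sum(a == cell_type & b == cell_type) / denom
}

#' Jaccard index of two methods' assignments of one cell type
#'
#' Intersection over union of the barcode sets each method assigns to the
#' type; symmetric in the pair.
#'
#' @inheritParams asymmetric_overlap
#' @return Value in `[0, 1]`, or NA when the union is empty.
#' @export
jaccard_per_type <- function(labels_a, labels_b, cell_type) {
  stopifnot(length(labels_a) == length(labels_b))
  ok <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[ok] == cell_type
  b <- labels_b[ok] == cell_type
  u <- sum(a | b)
  if (u == 0L) return(NA_real_)
  sum(a & b) / u
}

#' Mean per-type Jaccard between two annotation methods
#'
#' Unweighted mean of [jaccard_per_type()] over every type assigned by at
#' least one method (optionally weighted by union size).
#'
#' @inheritParams asymmetric_overlap
#' @param weighted Weight each type by its union size instead of equally.
#' @return List with `per_type` (named vector) and `mean`.
#' @export
mean_jaccard <- function(labels_a, labels_b, weighted = FALSE) {
  ok <- !is.na(labels_a) & !is.na(labels_b)
  types <- sort(unique(c(labels_a[ok], labels_b[ok])))
  per <- vapply(types, function(tt) {
    jaccard_per_type(labels_a, labels_b, tt)
  }, numeric(1))
  if (weighted) {
    w <- vapply(types, function(tt) {
      sum(labels_a[ok] == tt | labels_b[ok] == tt)
    }, numeric(1))
    m <- sum(per * w, na.rm = TRUE) / sum(w[!is.na(per)])
  } else {
    m <- mean(per, na.rm = TRUE)
  }
  list(per_type = per, mean = m)
}

#' Weighted (Ruzicka) Jaccard similarity of two composition vectors
#'
#' `sum(min(p, q)) / sum(max(p, q))` over a shared type universe; 1 iff the
#' compositions are equal, 0 for disjoint support. This min/max form is the
#' standard proportion-aware "weighted Jaccard".
#'
#' @param p,q Named non-negative proportion vectors summing to 1 (types
#'   missing from one vector count as 0).
#' @return Value in `[0, 1]`, NA if both vectors are all zero.
#' @export
weighted_jaccard <- function(p, q) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    types <- union(names(p), names(q))
    p <- stats::setNames(p[types], types); p[is.na(p)] <- 0
    q <- stats::setNames(q[types], types); q[is.na(q)] <- 0
  }
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  den <- sum(pmax(p, q))
  if (den == 0) return(NA_real_)
  sum(pmin(p, q)) / den
}

#' Cell-type composition vectors per donor, modality and method
#'
#' @param labels Harmonized label data.frame (`barcode` + method columns).
#' @param barcodes Data.frame with `barcode`, `donor_id`, `modality`.
#' @return List with `vectors` (named list of per-type proportion vectors,
#'   keyed `donor|modality|method`) and `percent` (long data.frame of
#'   percentages pooled across donors, per modality x method x type).
#' @export
composition_table <- function(labels, barcodes) {
  df <- merge(labels, barcodes[, c("barcode", "donor_id", "modality")],
              by = "barcode")
  methods_cols <- setdiff(names(labels), "barcode")
  vectors <- list()
  pct_rows <- list()
  for (meth in methods_cols) {
    for (donor in unique(df$donor_id)) {
      for (mod in unique(df$modality)) {
        sub <- df[df$donor_id == donor & df$modality == mod, meth]
        sub <- sub[!is.na(sub)]
        if (!length(sub)) next
        tab <- table(sub) / length(sub)
        vectors[[paste(donor, mod, meth, sep = "|")]] <-
          stats::setNames(as.numeric(tab), names(tab))
      }
    }
    for (mod in unique(df$modality)) {
      sub <- df[df$modality == mod, meth]
      sub <- sub[!is.na(sub)]
      tab <- 100 * table(sub) / length(sub)
      pct_rows[[paste(meth, mod)]] <- data.frame(
        method = meth, modality = mod, cell_type = names(tab),
        percent = as.numeric(tab), stringsAsFactors = FALSE)
    }
  }
  list(vectors = vectors,
       percent = do.call(rbind, c(pct_rows, make.row.names = FALSE)))
}

#' Median/quartile summaries of prediction or mapping scores
#'
#' @param scores Numeric vector in `[0, 1]`.
#' @param labels Optional cell-type labels for per-type summaries.
#' @return Data.frame with rows `overall` and one per type: `n`, `q1`,
#'   `median`, `q3` (type-7 quantiles).
#' @export
score_summary <- function(scores, labels = NULL) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]")
  }
  row <- function(name, x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
    data.frame(scope = name, n = sum(!is.na(x)), q1 = q[[1L]],
               median = q[[2L]], q3 = q[[3L]], stringsAsFactors = FALSE)
  }
  out <- list(row("overall", scores))
  if (!is.null(labels)) {
    for (tt in sort(unique(stats::na.omit(labels)))) {
      out[[tt]] <- row(tt, scores[!is.na(labels) & labels == tt])
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Full pairwise concordance report between annotation methods
#'
#' @param labels Harmonized label data.frame (`barcode` + method columns).
#' @param barcodes Optional barcode data.frame (`barcode`, `donor_id`,
#'   `modality`) enabling per-donor weighted-Jaccard blocks.
#' @param scores Optional score data.frame matching `labels`.
#' @return A `concordance_report` list: `overlap` (long data.frame of
#'   asymmetric overlaps per ordered method pair x type), `jaccard` (long
#'   per-pair x type), `mean_jaccard` (per pair), `weighted_jaccard`
#'   (per donor: modality-vs-modality within method, and method-vs-method
#'   within modality), `score_summaries`.
#' @export
concordance_report <- function(labels, barcodes = NULL, scores = NULL) {
  meths <- setdiff(names(labels), "barcode")
  types <- sort(unique(stats::na.omit(unlist(labels[meths]))))
  ov <- list(); jc <- list(); mj <- list()
  for (a in meths) for (b in meths) {
    if (a == b) next
    for (tt in types) {
      ov[[paste(a, b, tt)]] <- data.frame(
        from = a, to = b, cell_type = tt,
        overlap_pct = asymmetric_overlap(labels[[a]], labels[[b]], tt),
        stringsAsFactors = FALSE)
    }
    if (a < b) {
      m <- mean_jaccard(labels[[a]], labels[[b]])
      jc[[paste(a, b)]] <- data.frame(
        method_a = a, method_b = b, cell_type = names(m$per_type),
        jaccard = as.numeric(m$per_type), stringsAsFactors = FALSE)
      mj[[paste(a, b)]] <- data.frame(
        method_a = a, method_b = b, mean_jaccard = m$mean,
        stringsAsFactors = FALSE)
    }
  }
  wj <- NULL
  if (!is.null(barcodes)) {
    comp <- composition_table(labels, barcodes)$vectors
    key <- do.call(rbind, strsplit(names(comp), "|", fixed = TRUE))
    wj_rows <- list()
    # modality contrast within each donor x method
    for (meth in meths) for (donor in unique(key[, 1L])) {
      ka <- paste(donor, "cell", meth, sep = "|")
      kb <- paste(donor, "nucleus", meth, sep = "|")
      if (ka %in% names(comp) && kb %in% names(comp)) {
        wj_rows[[paste(donor, meth)]] <- data.frame(
          donor_id = donor, context = paste0("cell_vs_nucleus:", meth),
          weighted_jaccard = weighted_jaccard(comp[[ka]], comp[[kb]]),
          stringsAsFactors = FALSE)
      }
    }
    # method contrast within each donor x modality
    for (donor in unique(key[, 1L])) for (mod in unique(key[, 2L])) {
      for (a in meths) for (b in meths) {
        if (a >= b) next
        ka <- paste(donor, mod, a, sep = "|")
        kb <- paste(donor, mod, b, sep = "|")
        if (ka %in% names(comp) && kb %in% names(comp)) {
          wj_rows[[paste(donor, mod, a, b)]] <- data.frame(
            donor_id = donor,
            context = paste0(mod, ":", a, "_vs_", b),
            weighted_jaccard = weighted_jaccard(comp[[ka]], comp[[kb]]),
            stringsAsFactors = FALSE)
        }
      }
    }
    wj <- do.call(rbind, c(wj_rows, make.row.names = FALSE))
  }
  sc <- NULL
  if (!is.null(scores)) {
    sc_rows <- list()
    for (meth in intersect(meths, names(scores))) {
      s <- score_summary(scores[[meth]], labels[[meth]])
      s$method <- meth
      sc_rows[[meth]] <- s
    }
    sc <- do.call(rbind, c(sc_rows, make.row.names = FALSE))
  }
  structure(list(overlap = do.call(rbind, c(ov, make.row.names = FALSE)),
                 jaccard = do.call(rbind, c(jc, make.row.names = FALSE)),
                 mean_jaccard = do.call(rbind, c(mj,
                                                 make.row.names = FALSE)),
                 weighted_jaccard = wj, score_summaries = sc),
            class = "concordance_report")
}
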