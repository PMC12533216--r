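#' Describe one sample's on-disk CellRanger-style matrix triplet
#'
#' A sample is one donor x modality library stored as a MatrixMarket counts
#' file plus one-identifier-per-line features and barcodes files.
#'
#' @param sample_id Unique sample identifier within a run.
#' @param donor_id Donor the sample came from.
#' @param modality Either `"cell"` (scRNA-seq) or `"nucleus"` (snRNA-seq).
#' @param matrix_path Path to the MatrixMarket coordinate integer file.
#' @param features_path Path to the features TSV (first column is the key;
#'   optional second/third columns carry symbol and type).
#' @param barcodes_path Path to the barcodes file, one barcode per line.
#' @param ambient_fraction Optional per-sample ambient RNA fraction estimate
#'   in `[0, 1]` (consumed as metadata; ambient estimation itself is out of
#'   scope here).
#' @param intronic_fraction Optional per-sample intronic read fraction,
#'   pass-through metadata.
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(sample_id, donor_id, modality,
                        matrix_path, features_path, barcodes_path,
                        ambient_fraction = NA_real_,
                        intronic_fraction = NA_real_) {
  modality <- match.arg(modality, c("cell", "nucleus"))
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.na(ambient_fraction) &&
      (ambient_fraction < 0 || ambient_fraction > 1)) {
    stop("ambient_fraction must be in [0, 1] for sample ", sample_id)
  }
  structure(
    list(sample_id = sample_id, donor_id = donor_id, modality = modality,
         matrix_path = matrix_path, features_path = features_path,
         barcodes_path = barcodes_path,
         ambient_fraction = ambient_fraction,
         intronic_fraction = intronic_fraction),
    class = "sample_spec")
}

#' Read a CellRanger-style MTX triplet into a sparse UMI matrix
#'
#' Rows are features in file order, columns are barcodes in file order.
#' Entries must be non-negative integers; the features/barcodes files must
#' match the declared matrix dimensions.
#'
#' @param spec A [sample_spec()].
#' @return A `dgCMatrix` (genes x barcodes) with dimnames set, carrying
#'   `sample_id`, `donor_id` and `modality` attributes.
#' @export
read_mtx_sample <- function(spec) {
  stopifnot(inherits(spec, "sample_spec"))
  for (p in c(spec$matrix_path, spec$features_path, spec$barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- tryCatch(Matrix::readMM(spec$matrix_path), error = function(e) {
    stop("malformed MatrixMarket file ", spec$matrix_path, ": ",
         conditionMessage(e))
  })
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && any(x < 0)) {
    stop("negative entry in ", spec$matrix_path)
  }
  if (length(x) && any(x != floor(x))) {
    stop("non-integer entry in ", spec$matrix_path)
  }
  feats <- utils::read.delim(spec$features_path, header = FALSE,
                             colClasses = "character")
  bcs <- utils::read.delim(spec$barcodes_path, header = FALSE,
                           colClasses = "character")
  if (nrow(feats) != nrow(m)) {
    stop("feature count (", nrow(feats), ") does not match matrix rows (",
         nrow(m), ") for ", spec$features_path)
  }
  if (nrow(bcs) != ncol(m)) {
    stop("barcode count (", nrow(bcs), ") does not match matrix columns (",
         ncol(m), ") for ", spec$barcodes_path)
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(feats[[1L]], bcs[[1L]])
  attr(m, "sample_id") <- spec$sample_id
  attr(m, "donor_id") <- spec$donor_id
  attr(m, "modality") <- spec$modality
  m
}

#' Write a UMI matrix as a CellRanger-style MTX triplet
#'
#' @param m Sparse genes x barcodes matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (matrix, features, barcodes).
#' @export
write_mtx_sample <- function(m, dir) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paths[1L])
  writeLines(rownames(m), paths[2L])
  writeLines(colnames(m), paths[3L])
  invisible(paths)
}

#' Write a result table as TSV or JSON
#'
#' Numbers are stored at full precision so that a read-back compares equal.
#'
#' @param rows A data.frame whose records share a field set.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "tsv") {
    out <- rows
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) {
        out[[j]] <- sprintf("%.17g", out[[j]])
        out[[j]][out[[j]] == "NA"] <- NA_character_
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("json output needs the jsonlite package")
    }
    jsonlite::write_json(rows, path, dataframe = "rows", digits = I(17),
                         na = "null")
  }
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return A data.frame.
#' @export
read_table_file <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, check.names = FALSE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("json input needs the jsonlite package")
    }
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Round half away from zero
#'
#' The convention used for printed percentages in the report tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
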