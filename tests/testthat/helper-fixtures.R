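# Shared fixtures, generated in code at test time.

tiny_profiles <- function() {
  islet_profiles(n_types = 4, markers_per_type = 3, n_nuclear = 4,
                 n_mito = 3, n_ribo = 4, n_genes = 60,
                 hormone_share = 0.5)
}

# Effects with no modality contrast: bias 1 everywhere, mito/ribo targets
# at their source fractions, no ambient, no doublets.
neutral_effect <- function(profiles = tiny_profiles(), ambient = 0,
                           doublets = 0, libsize_log_mean = 8) {
  mass <- vapply(split(profiles$rates[, 1], profiles$classes), sum,
                 numeric(1))
  modality_effect(detection_bias = c(canonical = 1, nuclear = 1,
                                     malat1 = 1),
                  mito_fraction_target = mass[["mito"]],
                  ribo_fraction_target = mass[["ribo"]],
                  ambient_fraction = ambient, doublet_rate = doublets,
                  libsize_log_mean = libsize_log_mean,
                  libsize_log_sd = 0.3)
}

rand_counts <- function(ng = 40, nb = 30, seed = 1, lambda = 0.6) {
  set.seed(seed)
  m <- matrix(stats::rpois(ng * nb, lambda), ng, nb,
              dimnames = list(paste0("G", seq_len(ng)),
                              paste0("B", seq_len(nb))))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

# One moderately sized paired simulation reused across test files.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_paired_dataset(n_donors = 2, n_barcodes = 300,
                                        seed = 42)
    }
    cache
  }
})
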