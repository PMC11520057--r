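# Small in-code fixtures shared across test files.

toy_multiome <- function() {
  multiome_counts(
    rna_counts = Matrix::sparseMatrix(i = c(1, 2, 3, 1), j = c(1, 1, 2, 4),
                                      x = c(1, 2, 5, 5), dims = c(3, 4)),
    atac_counts = Matrix::sparseMatrix(i = c(1, 2, 2), j = c(1, 3, 4),
                                       x = c(4, 9, 2), dims = c(2, 4)),
    barcodes = paste0("BC", 1:4),
    gene_ids = paste0("gene", 1:3),
    region_ids = paste0("region", 1:2)
  )
}

# multiome_counts whose per-barcode totals are exactly the given vectors
# (one feature per modality).
totals_multiome <- function(t_rna, t_atac, barcodes = NULL) {
  n <- length(t_rna)
  if (is.null(barcodes)) barcodes <- paste0("BC", seq_len(n))
  multiome_counts(
    rna_counts = Matrix::Matrix(matrix(t_rna, nrow = 1), sparse = TRUE),
    atac_counts = Matrix::Matrix(matrix(t_atac, nrow = 1), sparse = TRUE),
    barcodes = barcodes, gene_ids = "g1", region_ids = "r1"
  )
}

fake_pvalues <- function(modality, tested, p, n_iters = 1000L) {
  structure(list(modality = modality, tested = tested, p_values = p,
                 m_c = rep(NA_integer_, length(p)), n_iters = n_iters),
            class = "modality_pvalues")
}

fake_lines <- function(kmeans_offset, lower_offset, upper_offset,
                       w = c(atac = 1, rna = 1) / sqrt(2)) {
  structure(list(normal = w, kmeans_offset = kmeans_offset,
                 lower_offset = lower_offset, upper_offset = upper_offset,
                 centroids = NULL, slope = -w[[1]] / w[[2]],
                 kmeans_intercept = kmeans_offset / w[[2]],
                 lower_intercept = lower_offset / w[[2]],
                 upper_intercept = upper_offset / w[[2]],
                 top_percentile = 99),
            class = "retention_lines")
}

# Tiny simulation configuration for fast integration tests.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 300L, n_regions = 500L, n_technical = 800L,
             n_ambient = 1200L, g1 = 150L, g2 = 50L, n_amplified = 50L,
             seed = seed, ...)
}
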