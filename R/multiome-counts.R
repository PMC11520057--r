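#' Paired multiome count matrices
#'
#' Container for an unfiltered feature-by-barcode count matrix pair as produced
#' by droplet multiome pipelines: one gene-by-barcode RNA matrix and one
#' region-by-barcode ATAC matrix sharing a single ordered barcode axis.
#'
#' @param rna_counts Sparse (or dense) non-negative integer matrix,
#'   genes x barcodes.
#' @param atac_counts Sparse (or dense) non-negative integer matrix,
#'   regions x barcodes. Must have the same number of columns, in the same
#'   barcode order, as `rna_counts`.
#' @param barcodes Character vector of unique droplet barcodes. Defaults to
#'   the column names of `rna_counts`.
#' @param gene_ids,region_ids Character vectors of unique feature identifiers.
#'   Default to the row names of the respective matrix.
#'
#' @return An object of class `multiome_counts`: a list with elements
#'   `rna`, `atac` (both `dgCMatrix`), `barcodes`, `gene_ids`, `region_ids`.
#' @export
multiome_counts <- function(rna_counts, atac_counts,
                            barcodes = colnames(rna_counts),
                            gene_ids = rownames(rna_counts),
                            region_ids = rownames(atac_counts)) {
  rna <- .as_count_matrix(rna_counts, "rna_counts")
  atac <- .as_count_matrix(atac_counts, "atac_counts")
  if (ncol(rna) != ncol(atac)) {
    stop("rna_counts and atac_counts must share one barcode axis: ",
         ncol(rna), " vs ", ncol(atac), " columns", call. = FALSE)
  }
  if (is.null(barcodes)) barcodes <- paste0("BC", seq_len(ncol(rna)))
  barcodes <- as.character(barcodes)
  if (length(barcodes) != ncol(rna)) {
    stop("length(barcodes) must equal the number of matrix columns",
         call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcodes are not allowed: e.g. ",
         paste(head(unique(barcodes[duplicated(barcodes)]), 3), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(rna)))
  if (is.null(region_ids)) region_ids <- paste0("region", seq_len(nrow(atac)))
  gene_ids <- as.character(gene_ids)
  region_ids <- as.character(region_ids)
  if (length(gene_ids) != nrow(rna) || anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique and match nrow(rna_counts)", call. = FALSE)
  }
  if (length(region_ids) != nrow(atac) || anyDuplicated(region_ids)) {
    stop("region_ids must be unique and match nrow(atac_counts)", call. = FALSE)
  }
  dimnames(rna) <- list(gene_ids, barcodes)
  dimnames(atac) <- list(region_ids, barcodes)
  structure(
    list(rna = rna, atac = atac, barcodes = barcodes,
         gene_ids = gene_ids, region_ids = region_ids),
    class = "multiome_counts"
  )
}

.as_count_matrix <- function(m, what) {
  if (is.matrix(m)) m <- as(m, "CsparseMatrix")
  if (!is(m, "CsparseMatrix")) m <- as(as(m, "dMatrix"), "CsparseMatrix")
  m <- as(m, "generalMatrix")
  x <- m@x
  if (any(!is.finite(x))) {
    stop(what, ": matrix entries must be finite", call. = FALSE)
  }
  if (any(x < 0)) {
    stop(what, ": negative counts are not allowed", call. = FALSE)
  }
  if (any(x != round(x))) {
    stop(what, ": non-integer counts are not allowed", call. = FALSE)
  }
  m
}

#' @export
print.multiome_counts <- function(x, ...) {
  cat("multiome_counts:", length(x$barcodes), "barcodes\n")
  cat("  RNA : ", nrow(x$rna), " genes, ", sum(x$rna@x), " counts\n", sep = "")
  cat("  ATAC: ", nrow(x$atac), " regions, ", sum(x$atac@x), " counts\n",
      sep = "")
  invisible(x)
}

#' Per-barcode library sizes
#'
#' Column totals of both modalities: `t_atac[c]` and `t_rna[c]` are the total
#' ATAC and RNA counts of barcode `c`.
#'
#' @param mc A [multiome_counts()] object.
#' @return A data.frame with columns `barcode`, `t_atac`, `t_rna`, one row per
#'   barcode in the original order.
#' @export
library_sizes <- function(mc) {
  stopifnot(is(mc, "multiome_counts"))
  data.frame(
    barcode = mc$barcodes,
    t_atac = as.numeric(Matrix::colSums(mc$atac)),
    t_rna = as.numeric(Matrix::colSums(mc$rna)),
    stringsAsFactors = FALSE
  )
}

#' Subset a multiome_counts object by barcode
#'
#' @param mc A [multiome_counts()] object.
#' @param idx Integer, logical or character index into the barcode axis.
#' @return A [multiome_counts()] object restricted to the selected barcodes.
#' @export
subset_barcodes <- function(mc, idx) {
  stopifnot(is(mc, "multiome_counts"))
  if (is.character(idx)) idx <- match(idx, mc$barcodes)
  if (anyNA(idx)) stop("unknown barcodes in subset", call. = FALSE)
  multiome_counts(mc$rna[, idx, drop = FALSE], mc$atac[, idx, drop = FALSE],
                  barcodes = mc$barcodes[idx],
                  gene_ids = mc$gene_ids, region_ids = mc$region_ids)
}
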