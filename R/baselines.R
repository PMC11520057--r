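#' Shiftable k-means-line baseline caller
#'
#' Emulates the count-space step of library-size thresholding pipelines: a
#' k-means (k = 2) fit in `(log10 t_atac, log10 t_rna)` space over barcodes
#' with positive totals in both modalities, with the decision line taken as
#' the perpendicular bisector of the two centroids. Barcodes on the high-count
#' side of the line shifted parallel by `intercept_shift` are called;
#' `intercept_shift = 0` is the unmodified baseline, and the called set is
#' nested (monotone) in the shift.
#'
#' @param t_atac,t_rna Per-barcode library sizes (same length).
#' @param intercept_shift Parallel shift of the line in signed-distance units
#'   (positive = stricter).
#' @param seed Seed for the k-means restarts.
#' @param fit_subset Optional logical vector selecting the barcodes the
#'   k-means is fitted on (e.g. barcodes above the technical-error
#'   boundaries, mirroring the junk removal that precedes count thresholding
#'   in production pipelines). Calls are still evaluated for every barcode.
#'   Default: all barcodes with positive totals in both modalities.
#' @return Logical vector of calls (barcodes with a zero total in either
#'   modality are never called); attribute `line` holds the unit normal and
#'   the unshifted offset, attribute `signed_distance` the per-barcode signed
#'   distances from the unshifted line.
#' @export
kmeans_line_caller <- function(t_atac, t_rna, intercept_shift = 0,
                               seed = 1L, fit_subset = NULL) {
  stopifnot(length(t_atac) == length(t_rna))
  use <- t_atac > 0 & t_rna > 0
  if (!is.null(fit_subset)) {
    stopifnot(is.logical(fit_subset), length(fit_subset) == length(t_atac))
    use <- use & fit_subset
  }
  if (sum(use) < 2L) {
    stop("need at least 2 barcodes with positive totals in both modalities",
         call. = FALSE)
  }
  pts <- cbind(log10(t_atac[use]), log10(t_rna[use]))
  set.seed(seed)
  km <- kmeans(pts, centers = 2L, nstart = 10L)
  cen <- km$centers
  if (sqrt(sum((cen[1, ] - cen[2, ])^2)) < 1e-8) {
    stop("degenerate clustering: coincident centroids", call. = FALSE)
  }
  hi <- which.max(rowSums(cen))
  d <- cen[hi, ] - cen[3L - hi, ]
  w <- d / sqrt(sum(d^2))
  c0 <- sum(w * colMeans(cen))
  s <- w[1] * log10(t_atac) + w[2] * log10(t_rna) - c0
  called <- is.finite(s) & s > intercept_shift
  attr(called, "line") <- list(normal = c(atac = w[1], rna = w[2]),
                               offset = c0, centroids = cen)
  attr(called, "signed_distance") <- s
  called
}

#' RNA-only (EmptyDrops-style) caller from a call table
#'
#' Thresholds the `FDR_RNA` column of a [call_cells()] table: the
#' EmptyDrops approach applied with the soup profiled from the RNA ambient
#' cluster, ignoring the ATAC modality.
#'
#' @param call_table A [call_cells()] data.frame (must contain `FDR_RNA`).
#' @param fdr_threshold Calling threshold (default 0.001).
#' @return Named logical vector over the table's barcodes (`NA` `FDR_RNA`,
#'   i.e. RNA-untested barcodes, are not called).
#' @export
rna_only_caller <- function(call_table, fdr_threshold = 0.001) {
  if (!"FDR_RNA" %in% names(call_table)) {
    stop("call table lacks an FDR_RNA column", call. = FALSE)
  }
  called <- !is.na(call_table$FDR_RNA) & call_table$FDR_RNA <= fdr_threshold
  names(called) <- call_table$barcode
  called
}

#' ROC curve of a scored caller against simulation truth
#'
#' Sweeps a threshold over the achieved scores (larger score = more
#' cell-like; a caller is "called at threshold s" when `score >= s`).
#' True-positive rate is computed over barcodes with labels in
#' `positive_labels`, false-positive rate over all other barcodes (empties,
#' amplified empties and technical barcodes all count as negatives). The
#' curve always includes the (0, 0) and (1, 1) endpoints; AUC is the
#' trapezoidal area over (FPR, TPR).
#'
#' @param scores Numeric vector (use `-Inf` for barcodes a caller can never
#'   call).
#' @param truth Data.frame with `label`, aligned with `scores` (or a
#'   character vector of labels).
#' @param positive_labels Labels counted as true cells.
#' @return Object of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `n_pos`, `n_neg`, `positive_labels`.
#' @export
roc_curve <- function(scores, truth,
                      positive_labels = c("nucleus", "small_nucleus")) {
  labels <- if (is.data.frame(truth)) truth$label else as.character(truth)
  stopifnot(length(scores) == length(labels))
  pos <- labels %in% positive_labels
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # collapse tied scores
  thresholds <- sc[last]
  tpr <- tp[last] / n_pos
  fpr <- fp[last] / n_neg
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  thresholds <- c(Inf, thresholds)
  if (tpr[length(tpr)] < 1 || fpr[length(fpr)] < 1) {
    tpr <- c(tpr, 1)
    fpr <- c(fpr, 1)
    thresholds <- c(thresholds, -Inf)
  }
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg,
                 positive_labels = positive_labels),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve: AUC =", round(x$auc, 4), "over", x$n_pos, "positives /",
      x$n_neg, "negatives\n")
  invisible(x)
}

#' Confusion metrics of a caller against simulation truth
#'
#' @param called Logical vector of calls aligned with `truth` (or named by
#'   barcode, matched on `truth$barcode`).
#' @param truth Data.frame with `barcode` and `label`.
#' @param positive_labels Labels counted as true cells.
#' @return One-row data.frame: `n_called`, `tpr`, `fpr`, `fdp` (empirical
#'   false-discovery proportion; 0 when nothing is called).
#' @export
evaluate_calls <- function(called, truth,
                           positive_labels = c("nucleus", "small_nucleus")) {
  if (!is.null(names(called)) && !is.null(truth$barcode)) {
    m <- match(truth$barcode, names(called))
    called <- ifelse(is.na(m), FALSE, called[m])
  }
  stopifnot(length(called) == nrow(truth))
  pos <- truth$label %in% positive_labels
  n_called <- sum(called)
  data.frame(
    n_called = n_called,
    tpr = if (any(pos)) sum(called & pos) / sum(pos) else NA_real_,
    fpr = if (any(!pos)) sum(called & !pos) / sum(!pos) else NA_real_,
    fdp = if (n_called > 0) sum(called & !pos) / n_called else 0
  )
}
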