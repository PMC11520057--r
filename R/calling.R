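#' Aggregate the RNA and ATAC p-values of a droplet
#'
#' The two per-modality p-values are combined by their arithmetic mean, which
#' remains a valid combination under arbitrary dependence between the
#' modalities. A droplet tested in only one modality contributes `p = 1` for
#' the absent modality before averaging (conservative: single-modality
#' evidence is penalized). `multiplier = 2` gives the strictly
#' validity-guaranteed averaged-p rule; the default `multiplier = 1` is the
#' plain mean.
#'
#' @param p_rna,p_atac Numeric vectors in `(0, 1]`; `NA` marks an untested
#'   modality. Recycled to a common length.
#' @param multiplier Scale applied to the mean before capping at 1.
#' @return Aggregated p-values; `NA` where both modalities are untested.
#' @export
aggregate_pvalues <- function(p_rna, p_atac, multiplier = 1) {
  n <- max(length(p_rna), length(p_atac))
  p_rna <- rep_len(as.numeric(p_rna), n)
  p_atac <- rep_len(as.numeric(p_atac), n)
  ok <- function(p) is.na(p) | (p > 0 & p <= 1)
  if (!all(ok(p_rna)) || !all(ok(p_atac))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  both_na <- is.na(p_rna) & is.na(p_atac)
  a <- ifelse(is.na(p_rna), 1, p_rna)
  b <- ifelse(is.na(p_atac), 1, p_atac)
  out <- pmin(1, multiplier * (a + b) / 2)
  out[both_na] <- NA_real_
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted values (`stats::p.adjust(method = "BH")`) with
#' input validation: all p-values must lie in `(0, 1]`.
#'
#' @param p Non-empty numeric vector in `(0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Fit the k-means line and its two parallel retention lines
#'
#' A k-means (k = 2) classifier in `(log10 t_atac, log10 t_rna)` space —
#' restricted to barcodes above both technical-error boundaries — separates
#' putative nuclei from smaller droplets. The "k-means line" is the
#' perpendicular bisector of the two centroids. Two parallel lines are
#' derived: a lower line through `(log10 l_atac, log10 l_rna)` (droplets below
#' it are never called) and an upper line 2/3 of the way from the k-means
#' line to the `top_percentile`-th percentile of the signed distances of the
#' droplets from the k-means line (droplets above it can optionally always be
#' retained).
#'
#' @param t_atac,t_rna Per-barcode library sizes.
#' @param model_atac,model_rna Fitted [fit_library_size_model()] objects (or
#'   lists with `b` and `l`).
#' @param top_percentile Percentile of signed distances anchoring the upper
#'   line (default 99).
#' @param seed Seed for the k-means restarts.
#' @return Object of class `retention_lines`: unit `normal` (pointing toward
#'   high counts), `kmeans_offset`, `lower_offset`, `upper_offset`,
#'   `centroids`, and slope/intercepts in `log10 t_rna = slope * log10 t_atac
#'   + intercept` form.
#' @export
fit_retention_lines <- function(t_atac, t_rna, model_atac, model_rna,
                                top_percentile = 99, seed = 1L) {
  stopifnot(length(t_atac) == length(t_rna))
  use <- t_atac > model_atac$b & t_rna > model_rna$b
  if (sum(use) < 2L) {
    stop("need at least 2 barcodes above both technical-error boundaries",
         call. = FALSE)
  }
  pts <- cbind(log10(t_atac[use]), log10(t_rna[use]))
  set.seed(seed)
  km <- kmeans(pts, centers = 2L, nstart = 10L)
  cen <- km$centers
  if (sqrt(sum((cen[1, ] - cen[2, ])^2)) < 1e-8) {
    stop("k-means centroids coincide; specify the decision line manually",
         call. = FALSE)
  }
  hi <- which.max(rowSums(cen))
  d <- cen[hi, ] - cen[3L - hi, ]
  w <- d / sqrt(sum(d^2))  # unit normal, positive toward the nuclei centroid
  c0 <- sum(w * colMeans(cen))
  s <- as.numeric(pts %*% w)
  c_low <- sum(w * c(log10(model_atac$l), log10(model_rna$l)))
  p_top <- as.numeric(quantile(s, top_percentile / 100, names = FALSE))
  c_up <- c0 + (2 / 3) * (p_top - c0)
  if (c_up < c0) {
    warning("top-percentile offset fell below the k-means line; clamping ",
            "the upper line onto it", call. = FALSE)
    c_up <- c0
  }
  slope <- if (abs(w[2]) > 1e-12) -w[1] / w[2] else NA_real_
  structure(
    list(normal = c(atac = w[1], rna = w[2]),
         kmeans_offset = c0, lower_offset = c_low, upper_offset = c_up,
         centroids = cen[c(3L - hi, hi), , drop = FALSE],
         slope = slope,
         kmeans_intercept = if (is.na(slope)) NA_real_ else c0 / w[2],
         lower_intercept = if (is.na(slope)) NA_real_ else c_low / w[2],
         upper_intercept = if (is.na(slope)) NA_real_ else c_up / w[2],
         top_percentile = top_percentile),
    class = "retention_lines"
  )
}

#' @export
print.retention_lines <- function(x, ...) {
  cat("retention_lines in (log10 t_atac, log10 t_rna) space\n")
  cat(sprintf("  k-means line: offset %.3f (slope %.3f)\n", x$kmeans_offset,
              x$slope))
  cat(sprintf("  lower line  : offset %.3f (through (log10 l_A, log10 l_R))\n",
              x$lower_offset))
  cat(sprintf("  upper line  : offset %.3f (2/3 toward p%g)\n",
              x$upper_offset, x$top_percentile))
  invisible(x)
}

#' Signed distance of barcodes from the k-means line
#'
#' @param lines A [fit_retention_lines()] object.
#' @param t_atac,t_rna Library sizes.
#' @return Numeric vector `w . (log10 t_atac, log10 t_rna) - kmeans_offset`;
#'   positive on the nuclei side. Barcodes with a zero total map to `-Inf`.
#' @export
line_signed_distance <- function(lines, t_atac, t_rna) {
  lines$normal[["atac"]] * log10(t_atac) +
    lines$normal[["rna"]] * log10(t_rna) - lines$kmeans_offset
}

#' Call nuclei-containing droplets
#'
#' Assembles the final per-barcode call table. The tested universe consists of
#' barcodes tested in at least one modality (library size above that
#' modality's technical-error boundary). Aggregated p-values are BH-adjusted
#' over that universe into `FDR`; RNA-only p-values are BH-adjusted over the
#' RNA-tested subset into `FDR_RNA`. The retention-line overrides are then
#' applied to the adjusted values: `FDR` is forced to 1 below the lower line,
#' and — only when `retain_large = TRUE` — to 0 above the upper line. A
#' droplet is called (`is_cell`) when its post-override `FDR` does not exceed
#' `fdr_threshold` and it is not below the lower line.
#'
#' @param mc A [multiome_counts()] object.
#' @param pv_rna,pv_atac [mc_pvalues()] results for the two modalities.
#' @param lines A [fit_retention_lines()] object.
#' @param fdr_threshold Calling threshold on `FDR` (default 0.001).
#' @param retain_large Force `FDR = 0` above the upper line (default off).
#' @param multiplier Aggregation multiplier, see [aggregate_pvalues()].
#' @return A data.frame (one row per barcode in the tested universe) with
#'   columns `barcode`, `t_rna`, `t_atac`, `p_rna`, `p_atac`, `p_agg`, `FDR`,
#'   `FDR_RNA`, `below_lower`, `above_upper`, `is_cell`.
#' @export
call_cells <- function(mc, pv_rna, pv_atac, lines, fdr_threshold = 0.001,
                       retain_large = FALSE, multiplier = 1) {
  stopifnot(is(mc, "multiome_counts"))
  sizes <- library_sizes(mc)
  universe <- pv_rna$tested | pv_atac$tested
  if (!any(universe)) stop("no barcode is tested in either modality",
                           call. = FALSE)
  idx <- which(universe)
  p_rna <- pv_rna$p_values[idx]
  p_atac <- pv_atac$p_values[idx]
  p_agg <- aggregate_pvalues(p_rna, p_atac, multiplier = multiplier)
  fdr <- bh_adjust(p_agg)
  fdr_rna <- rep(NA_real_, length(idx))
  rna_tested <- !is.na(p_rna)
  if (any(rna_tested)) fdr_rna[rna_tested] <- bh_adjust(p_rna[rna_tested])

  sdist <- line_signed_distance(lines, sizes$t_atac[idx], sizes$t_rna[idx])
  below_lower <- sdist < (lines$lower_offset - lines$kmeans_offset)
  above_upper <- sdist > (lines$upper_offset - lines$kmeans_offset)
  fdr[below_lower] <- 1
  if (retain_large) fdr[above_upper] <- 0
  is_cell <- fdr <= fdr_threshold & !below_lower

  data.frame(
    barcode = sizes$barcode[idx],
    t_rna = sizes$t_rna[idx],
    t_atac = sizes$t_atac[idx],
    p_rna = p_rna,
    p_atac = p_atac,
    p_agg = p_agg,
    FDR = fdr,
    FDR_RNA = fdr_rna,
    below_lower = below_lower,
    above_upper = above_upper,
    is_cell = is_cell,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write the call table as TSV
#'
#' @param table A [call_cells()] data.frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_call_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
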