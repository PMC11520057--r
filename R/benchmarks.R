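#' Benchmark configurations and runners
#'
#' Frozen simulation designs used to characterize the caller on synthetic
#' data with known ground truth, plus runners that execute the full pipeline
#' and score it against the truth. Problem sizes are chosen so each runner
#' completes in minutes on one CPU; the methods vignette discusses the
#' designs.
#'
#' `sim_config_fdr_benchmark`: ~2,000 true nuclei (1,500 untouched + 500
#' downsampled/scrambled) against ~20,000 negative barcodes (12,000
#' technical, 7,500 ambient, 500 amplified empties).
#'
#' `sim_config_ordering_benchmark`: reduced-scale design (g1 = 500, g2 = 200)
#' for ROC comparisons between callers.
#'
#' @param seed Integer seed for the dataset.
#' @return A [sim_config()].
#' @export
sim_config_fdr_benchmark <- function(seed = 1L) {
  sim_config(n_technical = 12000L, n_ambient = 7500L,
             g1 = 1500L, g2 = 500L, n_amplified = 500L, seed = seed)
}

#' @rdname sim_config_fdr_benchmark
#' @export
sim_config_ordering_benchmark <- function(seed = 1L) {
  sim_config(n_technical = 3000L, n_ambient = 3000L,
             g1 = 500L, g2 = 200L, n_amplified = 300L, seed = seed)
}

#' @rdname sim_config_fdr_benchmark
#' @param ... Overrides passed to [sim_config_tiny_cells()].
#' @export
sim_config_tiny_cells_benchmark <- function(seed = 1L, ...) {
  # reduced cell scale; the ambient cluster dominates the cell populations,
  # as it does in real unfiltered matrices, which anchors the mixture fit
  sim_config_tiny_cells(seed = seed, g1 = 1000L, g2 = 1000L,
                        n_technical = 6000L, n_ambient = 9000L,
                        n_amplified = 300L, ...)
}

#' Empirical FDR control of the caller
#'
#' For each seed, generates the FDR-benchmark dataset, runs the full pipeline
#' at the nominal threshold and records the empirical false-discovery
#' proportion (fraction of called barcodes whose truth label is `empty`,
#' `amplified_empty` or `technical`; 0 when nothing is called) and the
#' true-positive rate.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param n_iters Monte-Carlo iterations per modality.
#' @param fdr_threshold Nominal calling threshold.
#' @param verbose Narrate progress.
#' @return Data.frame with one row per seed: `seed`, `n_barcodes`,
#'   `n_called`, `fdp`, `tpr`.
#' @export
benchmark_fdr_control <- function(seeds = 1:10, n_iters = 2000L,
                                  fdr_threshold = 0.001, verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    sim <- simulate_dataset(sim_config_fdr_benchmark(seed = s))
    res <- multiome_call(sim$counts, n_iters_rna = n_iters,
                         n_iters_atac = n_iters,
                         fdr_threshold = fdr_threshold, seed = s,
                         verbose = verbose)
    called <- setNames(res$table$is_cell, res$table$barcode)
    met <- evaluate_calls(called, sim$truth)
    data.frame(seed = s, n_barcodes = length(sim$counts$barcodes),
               n_called = met$n_called, fdp = met$fdp, tpr = met$tpr)
  })
  do.call(rbind, rows)
}

#' Method-ordering benchmark (ROC comparison of the three callers)
#'
#' For each seed, generates the reduced-scale ordering dataset, runs the
#' pipeline, and computes ROC AUCs for (i) the multiome caller (score
#' `-FDR`), (ii) the RNA-only caller (score `-FDR_RNA`), and (iii) the
#' shiftable k-means-line baseline (score = signed distance from the line).
#' Barcodes a caller can never call score `-Inf`.
#'
#' @inheritParams benchmark_fdr_control
#' @return Data.frame per seed: `auc_multiome`, `auc_rna_only`, `auc_line`.
#' @export
benchmark_method_ordering <- function(seeds = 1:10, n_iters = 2000L,
                                      verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    sim <- simulate_dataset(sim_config_ordering_benchmark(seed = s))
    res <- multiome_call(sim$counts, n_iters_rna = n_iters,
                         n_iters_atac = n_iters, seed = s, verbose = verbose)
    sc <- .caller_scores(res, sim)
    data.frame(seed = s,
               auc_multiome = roc_curve(sc$multiome, sim$truth)$auc,
               auc_rna_only = roc_curve(sc$rna_only, sim$truth)$auc,
               auc_line = roc_curve(sc$line, sim$truth)$auc)
  })
  do.call(rbind, rows)
}

.caller_scores <- function(res, sim) {
  truth <- sim$truth
  m <- match(truth$barcode, res$table$barcode)
  fdr <- ifelse(is.na(m), NA, res$table$FDR[m])
  fdr_rna <- ifelse(is.na(m), NA, res$table$FDR_RNA[m])
  line <- .baseline_line_caller(res, sim)
  list(
    multiome = ifelse(is.na(fdr), -Inf, -fdr),
    rna_only = ifelse(is.na(fdr_rna), -Inf, -fdr_rna),
    line = ifelse(is.finite(attr(line, "signed_distance")),
                  attr(line, "signed_distance"), -Inf)
  )
}

# The baseline's k-means is fitted above the technical-error boundaries
# (count thresholding in production pipelines runs after junk-barcode
# removal); calls are still evaluated for every barcode.
.baseline_line_caller <- function(res, sim, intercept_shift = 0) {
  sizes <- library_sizes(sim$counts)
  sub <- sizes$t_atac > res$models$atac$b & sizes$t_rna > res$models$rna$b
  kmeans_line_caller(sizes$t_atac, sizes$t_rna,
                     intercept_shift = intercept_shift, seed = 1L,
                     fit_subset = sub)
}

#' Tiny-cells benchmark (small real cells below the k-means line)
#'
#' For each seed, generates the tiny-cells dataset (real nuclei downsampled
#' to 6% RNA / 2% ATAC library size), and records, for the `small_nucleus`
#' group: the fraction lying below the unshifted k-means line, the
#' true-positive rate of the line baseline on that below-line subset (a line
#' caller rejects everything below its line), the line baseline's overall
#' TPR, and the multiome caller's TPR at the given threshold.
#'
#' @inheritParams benchmark_fdr_control
#' @return Data.frame per seed: `frac_small_below`, `tpr_line_small_below`,
#'   `tpr_line_small`, `tpr_multiome_small`.
#' @export
benchmark_tiny_cells <- function(seeds = 1:10, n_iters = 10000L,
                                 fdr_threshold = 0.001, verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    sim <- simulate_dataset(sim_config_tiny_cells_benchmark(seed = s))
    small <- sim$truth$label == "small_nucleus"
    res <- multiome_call(sim$counts, n_iters_rna = n_iters,
                         n_iters_atac = n_iters,
                         fdr_threshold = fdr_threshold, seed = s,
                         verbose = verbose)
    line_called <- .baseline_line_caller(res, sim)
    below <- attr(line_called, "signed_distance") < 0
    called <- setNames(res$table$is_cell, res$table$barcode)
    m <- match(sim$truth$barcode, names(called))
    edm_called <- ifelse(is.na(m), FALSE, called[m])
    small_below <- small & below
    data.frame(seed = s,
               frac_small_below = mean(below[small]),
               tpr_line_small_below = if (any(small_below))
                 mean(line_called[small_below]) else NA_real_,
               tpr_line_small = mean(line_called[small]),
               tpr_multiome_small = mean(edm_called[small]))
  })
  do.call(rbind, rows)
}
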