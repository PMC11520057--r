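#' Full empty-droplet calling pipeline for multiome data
#'
#' Runs the complete caller on an unfiltered multiome matrix: per-modality
#' library-size mixture models (technical-error / ambient / nuclei clusters),
#' soup-profile construction with Good-Turing smoothing, over-dispersion
#' estimation, Monte-Carlo Dirichlet-multinomial p-values per modality,
#' arithmetic-mean aggregation, Benjamini-Hochberg correction, and the
#' k-means retention lines.
#'
#' All randomness derives from `seed`: the two Monte-Carlo runs use
#' `seed` (RNA) and `seed + 1` (ATAC), k-means uses `seed + 2`, the alpha
#' subsample `seed + 3`, and mixture-fit jitter retries `seed + 4`.
#'
#' @param input A [multiome_counts()] object or a directory path readable by
#'   [read_multiome_dir()].
#' @param gex_tag,atac_tag Feature-type tags for directory input.
#' @param n_iters_rna,n_iters_atac Monte-Carlo iterations per modality.
#' @param fdr_threshold Calling threshold on the aggregated FDR.
#' @param l_sigmas_rna,l_sigmas_atac Ambient-cluster widths (`NULL` =
#'   modality defaults 1.5 / 2).
#' @param b_rna,l_rna,b_atac,l_atac Optional manual boundary overrides (count
#'   scale).
#' @param retain_large Force FDR = 0 above the upper retention line.
#' @param multiplier Aggregation multiplier (see [aggregate_pvalues()]).
#' @param top_percentile Upper-line anchor percentile.
#' @param alpha_bounds Search bounds for the over-dispersion MLE.
#' @param alpha_max_droplets Soup-droplet cap for the MLE.
#' @param seed Integer master seed.
#' @param verbose Narrate the stages.
#' @return Object of class `multiome_call`: `table` (see [call_cells()]),
#'   `models`, `profiles`, `lines`, `pvalues`, and `report` (a serializable
#'   run summary).
#' @export
multiome_call <- function(input,
                          gex_tag = "Gene Expression", atac_tag = "Peaks",
                          n_iters_rna = 10000L, n_iters_atac = 10000L,
                          fdr_threshold = 0.001,
                          l_sigmas_rna = NULL, l_sigmas_atac = NULL,
                          b_rna = NULL, l_rna = NULL,
                          b_atac = NULL, l_atac = NULL,
                          retain_large = FALSE, multiplier = 1,
                          top_percentile = 99,
                          alpha_bounds = c(0.01, 1e4),
                          alpha_max_droplets = 2000L,
                          seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  mc <- if (is.character(input)) {
    say("reading multiome directory: ", input)
    read_multiome_dir(input, gex_tag = gex_tag, atac_tag = atac_tag)
  } else input
  stopifnot(is(mc, "multiome_counts"))
  sizes <- library_sizes(mc)

  fit_one <- function(totals, modality, l_sigmas, b_ovr, l_ovr) {
    model <- fit_library_size_model(totals, modality, l_sigmas = l_sigmas,
                                    seed = seed + 4L)
    if (!is.null(b_ovr)) model$b <- b_ovr
    if (!is.null(l_ovr)) model$l <- l_ovr
    if (model$b >= model$l) stop("override makes b >= l", call. = FALSE)
    say(sprintf("%s clusters: b = %.1f, l = %.1f (means %.2f / %.2f / %.2f)",
                modality, model$b, model$l, model$means[1], model$means[2],
                model$means[3]))
    model
  }
  model_rna <- fit_one(sizes$t_rna, "RNA", l_sigmas_rna, b_rna, l_rna)
  model_atac <- fit_one(sizes$t_atac, "ATAC", l_sigmas_atac, b_atac, l_atac)

  soup_rna <- soup_droplets(sizes$t_rna, model_rna)
  soup_atac <- soup_droplets(sizes$t_atac, model_atac)
  say("soup droplets: ", length(soup_rna), " RNA, ", length(soup_atac),
      " ATAC")

  prof_rna <- build_ambient_profile(mc, soup_rna, "RNA")
  prof_atac <- build_ambient_profile(mc, soup_atac, "ATAC")
  prof_rna$alpha <- estimate_alpha(mc$rna[, soup_rna, drop = FALSE],
                                   prof_rna$proportions,
                                   bounds = alpha_bounds,
                                   max_droplets = alpha_max_droplets,
                                   seed = seed + 3L)
  prof_atac$alpha <- estimate_alpha(mc$atac[, soup_atac, drop = FALSE],
                                    prof_atac$proportions,
                                    bounds = alpha_bounds,
                                    max_droplets = alpha_max_droplets,
                                    seed = seed + 3L)
  say(sprintf("over-dispersion alpha: RNA %.3g, ATAC %.3g", prof_rna$alpha,
              prof_atac$alpha))

  pv_rna <- mc_pvalues(mc, "RNA", prof_rna, model_rna,
                       mc_config(n_iters_rna, seed = seed))
  pv_atac <- mc_pvalues(mc, "ATAC", prof_atac, model_atac,
                        mc_config(n_iters_atac, seed = seed + 1L))
  say("tested barcodes: ", sum(pv_rna$tested), " RNA, ", sum(pv_atac$tested),
      " ATAC")

  lines <- fit_retention_lines(sizes$t_atac, sizes$t_rna, model_atac,
                               model_rna, top_percentile = top_percentile,
                               seed = seed + 2L)
  table <- call_cells(mc, pv_rna, pv_atac, lines,
                      fdr_threshold = fdr_threshold,
                      retain_large = retain_large, multiplier = multiplier)
  say("called ", sum(table$is_cell), " of ", nrow(table),
      " tested barcodes at FDR <= ", fdr_threshold)

  report <- list(
    package_version = as.character(packageVersion("dropletMultiome")),
    n_barcodes = length(mc$barcodes),
    n_genes = nrow(mc$rna), n_regions = nrow(mc$atac),
    seed = seed,
    n_iters = list(rna = n_iters_rna, atac = n_iters_atac),
    fdr_threshold = fdr_threshold, retain_large = retain_large,
    multiplier = multiplier, top_percentile = top_percentile,
    boundaries = list(rna = list(b = model_rna$b, l = model_rna$l),
                      atac = list(b = model_atac$b, l = model_atac$l)),
    alpha = list(rna = prof_rna$alpha, atac = prof_atac$alpha),
    n_soup = list(rna = length(soup_rna), atac = length(soup_atac)),
    n_tested = list(rna = sum(pv_rna$tested), atac = sum(pv_atac$tested),
                    universe = nrow(table)),
    n_called = sum(table$is_cell),
    lines = list(normal = as.list(lines$normal),
                 kmeans_offset = lines$kmeans_offset,
                 lower_offset = lines$lower_offset,
                 upper_offset = lines$upper_offset)
  )
  structure(list(table = table, models = list(rna = model_rna,
                                              atac = model_atac),
                 profiles = list(rna = prof_rna, atac = prof_atac),
                 pvalues = list(rna = pv_rna, atac = pv_atac),
                 lines = lines, report = report),
            class = "multiome_call")
}

#' @export
print.multiome_call <- function(x, ...) {
  r <- x$report
  cat("multiome_call on", r$n_barcodes, "barcodes\n")
  cat(sprintf("  RNA : b = %.1f, l = %.1f, alpha = %.3g, %d tested\n",
              r$boundaries$rna$b, r$boundaries$rna$l, r$alpha$rna,
              r$n_tested$rna))
  cat(sprintf("  ATAC: b = %.1f, l = %.1f, alpha = %.3g, %d tested\n",
              r$boundaries$atac$b, r$boundaries$atac$l, r$alpha$atac,
              r$n_tested$atac))
  cat(sprintf("  %d of %d universe barcodes called at FDR <= %g\n",
              r$n_called, r$n_tested$universe, r$fdr_threshold))
  invisible(x)
}

#' Write pipeline outputs
#'
#' Writes the call table (`calls.tsv`) and the JSON run report
#' (`report.json`) into a directory.
#'
#' @param result A [multiome_call()] result.
#' @param path Output directory.
#' @return Invisibly, `path`.
#' @export
write_call_outputs <- function(result, path) {
  stopifnot(is(result, "multiome_call"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_call_table(result$table, file.path(path, "calls.tsv"))
  jsonlite::write_json(result$report, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
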