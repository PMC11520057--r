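test_that("p-value aggregation is the capped arithmetic mean", {
  expect_equal(aggregate_pvalues(0.02, 0.04), 0.03)
  # an untested modality contributes p = 1 before averaging
  expect_equal(aggregate_pvalues(0.5, NA), 0.75)
  expect_equal(aggregate_pvalues(NA, 0.5), 0.75)
  expect_equal(aggregate_pvalues(1, 1, multiplier = 2), 1)
  expect_equal(aggregate_pvalues(0.1, 0.3, multiplier = 2), 0.4)
  expect_true(is.na(aggregate_pvalues(NA, NA)))
  expect_error(aggregate_pvalues(0, 0.5), "\\(0, 1\\]")
  expect_error(aggregate_pvalues(0.5, 1.2), "\\(0, 1\\]")
  # vectorized with recycling
  expect_equal(aggregate_pvalues(c(0.2, NA), c(0.4, 0.4)), c(0.3, 0.7))
})

test_that("BH adjustment matches the step-up oracle on all permutations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 1)), c(0.04, 0.04, 0.04, 1))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")

  base <- c(0.01, 0.2, 0.5, 1)
  perms <- expand.grid(1:4, 1:4, 1:4, 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  for (r in seq_len(nrow(perms))) {
    p <- base[as.numeric(perms[r, ])]
    expect_equal(bh_adjust(p), bh_oracle(p))
  }

  # idempotent on its own output's order statistics
  q <- bh_adjust(c(0.003, 0.04, 0.04, 0.3, 0.9))
  expect_equal(sort(bh_adjust(q)), sort(bh_oracle(q)))
})

test_that("retention lines bisect the centroids and anchor on (l_A, l_R)", {
  set.seed(1)
  t_atac <- 10^c(rnorm(400, 2, 0.1), rnorm(400, 4, 0.1))
  t_rna <- 10^c(rnorm(400, 1.5, 0.1), rnorm(400, 3.5, 0.1))
  model_atac <- list(b = 3, l = 400)
  model_rna <- list(b = 3, l = 150)
  lines <- fit_retention_lines(t_atac, t_rna, model_atac, model_rna)

  # perpendicular bisector: centroids at equal and opposite signed distance
  d1 <- sum(lines$normal * lines$centroids[1, ]) - lines$kmeans_offset
  d2 <- sum(lines$normal * lines$centroids[2, ]) - lines$kmeans_offset
  expect_equal(d1, -d2, tolerance = 1e-8)
  expect_lt(d1, 0)

  # the lower line passes exactly through (log10 l_A, log10 l_R)
  expect_equal(sum(lines$normal * log10(c(model_atac$l, model_rna$l))),
               lines$lower_offset, tolerance = 1e-12)
  # in slope/intercept form: at x = log10(l_A) the line returns log10(l_R)
  expect_equal(lines$slope * log10(model_atac$l) + lines$lower_intercept,
               log10(model_rna$l), tolerance = 1e-9)

  # upper line never sits below the k-means line
  expect_gte(lines$upper_offset, lines$kmeans_offset)

  expect_error(
    fit_retention_lines(rep(10, 50), rep(10, 50), model_atac, model_rna),
    "manual|distinct"
  )
})

test_that("call table enforces the retention-line overrides", {
  n <- 8
  t_rna <- c(2, 40, 50, 60, 5000, 80, 9000, 1)
  t_atac <- c(3, 50, 60, 50, 6000, 90, 8000, 1)
  mc <- totals_multiome(t_rna, t_atac)
  tested_rna <- t_rna > 5
  tested_atac <- t_atac > 5
  p_rna <- ifelse(tested_rna, c(NA, 0.5, 0.9, 1e-4, 1e-4, 0.2, 1e-4, NA), NA)
  p_atac <- ifelse(tested_atac, c(NA, 0.6, 0.8, 2e-4, 2e-4, 0.3, 2e-4, NA), NA)
  pv_rna <- fake_pvalues("RNA", tested_rna, p_rna)
  pv_atac <- fake_pvalues("ATAC", tested_atac, p_atac)
  # lower line above barcode 4 (log-sum ~ 3.5), below barcodes 5 and 7;
  # upper line between them
  lines <- fake_lines(kmeans_offset = 4, lower_offset = 4.2,
                      upper_offset = 5.2)

  tab <- call_cells(mc, pv_rna, pv_atac, lines, fdr_threshold = 0.05)
  expect_setequal(tab$barcode, paste0("BC", 2:7))  # 1 and 8 never tested
  expect_named(tab, c("barcode", "t_rna", "t_atac", "p_rna", "p_atac",
                      "p_agg", "FDR", "FDR_RNA", "below_lower", "above_upper",
                      "is_cell"))

  # below the lower line: FDR forced to 1 and never called, whatever p was
  expect_true(all(tab$FDR[tab$below_lower] == 1))
  expect_true(all(!tab$is_cell[tab$below_lower]))
  expect_true(tab$below_lower[tab$barcode == "BC4"])

  # retain-large off: above_upper droplets keep their adjusted values
  expect_true(any(tab$above_upper))
  tab_keep <- call_cells(mc, pv_rna, pv_atac, lines, fdr_threshold = 0.05,
                         retain_large = TRUE)
  expect_true(all(tab_keep$FDR[tab_keep$above_upper] == 0))
  expect_true(all(tab_keep$is_cell[tab_keep$above_upper]))
  # ablation: rows not above the upper line are untouched
  same <- !tab$above_upper
  expect_identical(tab$is_cell[same], tab_keep$is_cell[same])

  # threshold 1 calls everything not below the lower line
  tab1 <- call_cells(mc, pv_rna, pv_atac, lines, fdr_threshold = 1)
  expect_identical(tab1$is_cell, !tab1$below_lower)

  # lowering the threshold never adds calls
  tab_lo <- call_cells(mc, pv_rna, pv_atac, lines, fdr_threshold = 0.01)
  expect_true(all(tab_lo$barcode[tab_lo$is_cell] %in%
                  tab$barcode[tab$is_cell]))
})

test_that("FDR_RNA is adjusted over the RNA-tested subset", {
  t_rna <- c(10, 20, 30, 0)
  t_atac <- c(0, 15, 25, 40)
  mc <- totals_multiome(t_rna, t_atac)
  pv_rna <- fake_pvalues("RNA", t_rna > 5, c(0.01, 0.02, 0.03, NA))
  pv_atac <- fake_pvalues("ATAC", t_atac > 5, c(NA, 0.5, 0.6, 0.7))
  lines <- fake_lines(kmeans_offset = -10, lower_offset = -10,
                      upper_offset = 10)
  tab <- call_cells(mc, pv_rna, pv_atac, lines)
  rna_rows <- !is.na(tab$p_rna)
  expect_equal(tab$FDR_RNA[rna_rows], bh_oracle(tab$p_rna[rna_rows]))
  expect_true(all(is.na(tab$FDR_RNA[!rna_rows])))
})

test_that("well-separated nuclei are recovered with controlled error", {
  mets <- lapply(1:2, function(s) {
    sim <- simulate_dataset(sim_config_ordering_benchmark(seed = s))
    res <- multiome_call(sim$counts, n_iters_rna = 10000,
                         n_iters_atac = 10000, seed = s, verbose = FALSE)
    evaluate_calls(setNames(res$table$is_cell, res$table$barcode), sim$truth)
  })
  mets <- do.call(rbind, mets)
  expect_gte(mean(mets$tpr), 0.95)
  expect_lte(mean(mets$fdp), 0.01)
})
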