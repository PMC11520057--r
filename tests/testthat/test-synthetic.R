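test_that("generation is a pure function of the seed with exact bookkeeping", {
  cfg <- sim_config(n_genes = 100, n_regions = 150, n_technical = 300,
                    n_ambient = 300, g1 = 30, g2 = 10, n_amplified = 20,
                    seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$counts$rna == b$counts$rna))
  expect_true(all(a$counts$atac == b$counts$atac))

  cfg2 <- sim_config(n_genes = 100, n_regions = 150, n_technical = 300,
                     n_ambient = 300, g1 = 30, g2 = 10, n_amplified = 20,
                     seed = 6)
  c_ <- simulate_dataset(cfg2)
  expect_false(all(a$counts$rna == c_$counts$rna))

  tab <- table(a$truth$label)
  expect_equal(unname(tab[c("technical", "empty", "nucleus", "small_nucleus",
                            "amplified_empty")]),
               c(300L, 300L, 30L, 10L, 20L), ignore_attr = TRUE)
  expect_length(a$counts$barcodes, 300 + 300 + 30 + 10 + 20)
  expect_false(anyDuplicated(a$counts$barcodes) > 0)
})

test_that("a config without nuclei yields only technical and empty barcodes", {
  cfg <- sim_config(n_genes = 50, n_regions = 60, n_technical = 100,
                    n_ambient = 100, g1 = 0, g2 = 0, n_amplified = 0)
  base <- generate_base_dataset(cfg)
  expect_setequal(unique(base$truth$label), c("technical", "empty"))
  sim <- assemble_simulation(base, cfg)
  expect_setequal(unique(sim$truth$label), c("technical", "empty"))
})

test_that("empty-droplet totals land near the configured ambient mode", {
  cfg <- sim_config(n_genes = 300, n_regions = 300, n_technical = 10,
                    n_ambient = 2000, g1 = 0, g2 = 0, n_amplified = 0,
                    seed = 2)
  base <- generate_base_dataset(cfg)
  t_rna <- Matrix::colSums(base$counts$rna[, base$truth$label == "empty"])
  mode_hat <- 10^median(log10(t_rna))
  expect_lt(abs(log10(mode_hat) - cfg$ambient_logmean_rna), log10(1.5))
})

test_that("thinning is binomial and scrambling conserves totals", {
  cfg <- sim_config(n_genes = 200, n_regions = 200, n_technical = 20,
                    n_ambient = 50, g1 = 20, g2 = 0, n_amplified = 0,
                    seed = 3)
  base <- generate_base_dataset(cfg)
  mc <- base$counts
  nuc <- which(base$truth$label == "nucleus")

  # identity transform
  same <- downsample_and_scramble(mc, nuc, frac_rna = 1, frac_atac = 1,
                                  scramble_frac = 0, seed = 1)
  expect_true(all(same$rna == mc$rna))
  expect_true(all(same$atac == mc$atac))

  # binomial thinning: total within the CLT bound around frac * t
  t0 <- as.numeric(Matrix::colSums(mc$rna)[nuc])
  thin <- downsample_and_scramble(mc, nuc, frac_rna = 0.2, frac_atac = 0.2,
                                  scramble_frac = 0, seed = 2)
  t1 <- as.numeric(Matrix::colSums(thin$rna)[nuc])
  expect_true(all(abs(t1 - 0.2 * t0) < 3 * sqrt(t0 * 0.2 * 0.8) + 3))

  # scrambling reassigns identities but conserves each barcode's total
  scr <- downsample_and_scramble(mc, nuc, frac_rna = 1, frac_atac = 1,
                                 scramble_frac = 0.5, seed = 3)
  expect_equal(Matrix::colSums(scr$rna), Matrix::colSums(mc$rna))
  expect_equal(Matrix::colSums(scr$atac), Matrix::colSums(mc$atac))
  expect_false(all(scr$rna[, nuc] == mc$rna[, nuc]))
  # untouched barcodes stay untouched
  other <- setdiff(seq_along(mc$barcodes), nuc)
  expect_true(all(scr$rna[, other] == mc$rna[, other]))
})

test_that("amplified empties are integer multiples of their sources", {
  mc <- toy_multiome()
  amp2 <- amplify_empties(mc, 1:2, amp_range_rna = c(2, 2),
                          amp_range_atac = c(2, 2), n_out = 5, seed = 1)
  rec <- attr(amp2, "amplification")
  for (o in seq_len(5)) {
    src <- match(rec$source[o], mc$barcodes)
    expect_equal(amp2$rna[, o], 2 * mc$rna[, src])
    expect_equal(amp2$atac[, o], 2 * mc$atac[, src])
  }

  amp <- amplify_empties(mc, c(1L, 2L, 4L), n_out = 40, seed = 2)
  rec <- attr(amp, "amplification")
  expect_true(all(rec$k_rna %in% 2:10))
  expect_true(all(rec$k_atac %in% 2:40))
  t_out <- Matrix::colSums(amp$rna)
  t_src <- Matrix::colSums(mc$rna)[match(rec$source, mc$barcodes)]
  ratio <- unname(ifelse(t_src > 0, t_out / t_src, NA))
  expect_equal(ratio[!is.na(ratio)], rec$k_rna[!is.na(ratio)])
  expect_true(all(t_out <= 10 * max(t_src) & t_out >= 2 * min(t_src)))
})

test_that("the tiny-cells preset sets the stated downsampling rates", {
  cfg <- sim_config_tiny_cells(seed = 1)
  expect_equal(cfg$downsample_frac_rna, 0.06)
  expect_equal(cfg$downsample_frac_atac, 0.02)
  expect_equal(cfg$scramble_frac, 0)
  expect_equal(cfg$g1, 2000L)
  expect_equal(cfg$g2, 2000L)
})

test_that("tiny-cells small nuclei sit below the fitted k-means line", {
  sim <- simulate_dataset(sim_config_tiny_cells_benchmark(seed = 4))
  sz <- library_sizes(sim$counts)
  m_rna <- fit_library_size_model(sz$t_rna, "RNA")
  m_atac <- fit_library_size_model(sz$t_atac, "ATAC")
  sub <- sz$t_rna > m_rna$b & sz$t_atac > m_atac$b
  called <- kmeans_line_caller(sz$t_atac, sz$t_rna, fit_subset = sub)
  s <- attr(called, "signed_distance")
  small <- sim$truth$label == "small_nucleus"
  expect_lt(mean(s[small]), 0)
  expect_gt(mean(small & s < 0) / mean(small), 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(downsample_frac_rna = 0), "downsample")
  expect_error(sim_config(amp_range_rna = c(1, 10)), "amp_range")
  expect_error(sim_config(scramble_frac = 1.2), "scramble")
  cfg <- sim_config(n_technical = 10, n_ambient = 10, g1 = 5, g2 = 5)
  base <- generate_base_dataset(cfg)
  cfg_big <- sim_config(n_technical = 10, n_ambient = 10, g1 = 50, g2 = 5)
  expect_error(assemble_simulation(base, cfg_big), "g1 \\+ g2")
})
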