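test_that("log-likelihood matches closed forms", {
  # empty droplet: L = 1 exactly
  expect_identical(dm_log_likelihood(c(0, 0), c(0.5, 0.5), 3), 0)
  # one feature: telescoping gamma ratio, L = 1
  expect_equal(dm_log_likelihood(7, 1, 3), 0, tolerance = 1e-12)
  # beta-binomial(n = 2, a = 1, b = 1) is uniform on {0, 1, 2}: L = 1/3
  expect_equal(dm_log_likelihood(c(1, 1), c(0.5, 0.5), 2), log(1 / 3),
               tolerance = 1e-10)
  # impossible observation under a zero-probability feature
  expect_identical(dm_log_likelihood(c(1, 1), c(0, 1), 2), -Inf)
  expect_error(dm_log_likelihood(c(NA, 1), c(0.5, 0.5), 2), "NaN/NA")
  expect_error(dm_log_likelihood(c(1, 1), c(0.5, 0.4), 2), "sum to 1")
})

test_that("the pmf sums to one over all count vectors (enumeration)", {
  set.seed(7)
  for (n_feat in 2:3) {
    p <- rgamma(n_feat, 1)
    p <- p / sum(p)
    for (total in c(1, 3, 6)) {
      grid <- enumerate_count_vectors(n_feat, total)
      ll <- apply(grid, 1, dm_log_likelihood, proportions = p, alpha = 2.5)
      expect_equal(sum(exp(ll)), 1, tolerance = 1e-8)
    }
  }
})

test_that("Dirichlet-multinomial sampling has the right moments", {
  expect_identical(sample_dm_counts(0, c(0.3, 0.7), 5), integer(2))

  set.seed(11)
  x <- sample_dm_counts(1e5, c(0.3, 0.7), 1e6)
  expect_equal(sum(x), 1e5)
  # near-multinomial limit: CLT bound on the first-feature fraction
  expect_lt(abs(x[1] / 1e5 - 0.3), 3 * sqrt(0.21 / 1e5))

  # E[X / t] = p for any alpha
  p <- c(0.2, 0.5, 0.3)
  draws <- replicate(2000, sample_dm_counts(50, p, 5) / 50)
  se <- sqrt(p * (1 - p) * (1 + 49 / 6) / 50 / 2000)  # DM variance, alpha = 5
  expect_true(all(abs(rowMeans(draws) - p) < 4 * se))
})

test_that("alpha MLE recovers the generating value within 25%", {
  set.seed(1)
  p <- sgt_oracle(rpois(200, 3) + c(rep(1, 50), rep(0, 150)))
  alphas <- vapply(1:5, function(s) {
    set.seed(100 + s)
    totals <- pmax(1, rpois(2000, 100))
    counts <- dropletMultiome:::.sample_dm_matrix(totals, p, alpha = 50)
    estimate_alpha(counts, p, seed = s)
  }, numeric(1))
  expect_gte(median(alphas), 40)
  expect_lte(median(alphas), 62.5)
})

test_that("alpha MLE reports boundary solutions and beats its own grid", {
  set.seed(3)
  p <- rep(1 / 50, 50)
  # pure multinomial data: likelihood increases toward the alpha -> Inf limit
  counts <- sapply(1:200, function(i) rmultinom(1, 100, p))
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  expect_warning(a_hat <- estimate_alpha(counts, p), "upper")
  expect_equal(a_hat, 1e4)

  # interior optimum is at least as good as every coarse grid point
  set.seed(4)
  totals <- pmax(1, rpois(500, 80))
  counts <- dropletMultiome:::.sample_dm_matrix(totals, p, alpha = 20)
  a_hat <- estimate_alpha(counts, p, seed = 1)
  x <- counts@x
  i <- counts@i + 1L
  t_tot <- as.numeric(Matrix::colSums(counts))
  f <- function(a) dropletMultiome:::.dm_loglik_total(x, i, t_tot, p, a)
  grid <- exp(seq(log(0.01), log(1e4), length.out = 30))
  expect_gte(f(a_hat), max(vapply(grid, f, numeric(1))))
})

test_that("Monte-Carlo p-values follow the (m+1)/(M+1) formula and lattice", {
  # single feature: every simulated vector equals the observation, so ties
  # make m = M and p = 1
  mc1 <- totals_multiome(t_rna = c(0, 50, 80), t_atac = c(0, 0, 0))
  prof <- structure(list(modality = "RNA", proportions = 1, alpha = 10),
                    class = "ambient_profile")
  pv <- mc_pvalues(mc1, "RNA", prof, list(b = 5), mc_config(99, seed = 1))
  expect_true(all(pv$p_values[pv$tested] == 1))
  expect_true(is.na(pv$p_values[1]))  # below b: never tested

  # an observation far outside the soup gets the smallest attainable p
  set.seed(2)
  n_bc <- 40
  rna <- cbind(matrix(0, 2, n_bc))
  rna[1, 1] <- 500                      # all counts on a ~zero-prob feature
  rna[2, 2:n_bc] <- rpois(n_bc - 1, 450)
  mc2 <- multiome_counts(Matrix::Matrix(rna, sparse = TRUE),
                         Matrix::Matrix(0, 1, n_bc, sparse = TRUE))
  prof2 <- structure(list(modality = "RNA",
                          proportions = c(1e-6, 1 - 1e-6), alpha = 100),
                     class = "ambient_profile")
  pv2 <- mc_pvalues(mc2, "RNA", prof2, list(b = 5), mc_config(999, seed = 1))
  expect_equal(unname(pv2$p_values[1]), 1 / 1000)
  # p-values live on the lattice k/(M+1)
  k <- pv2$p_values[pv2$tested] * 1000
  expect_equal(k, round(k), tolerance = 1e-9)
  expect_true(all(pv2$p_values[pv2$tested] >= 1 / 1000 &
                  pv2$p_values[pv2$tested] <= 1))
})

test_that("p-values are deterministic in the seed", {
  set.seed(5)
  p <- as.numeric(sgt_oracle(rpois(100, 2) + rep(c(1, 0), c(30, 70))))
  totals <- pmax(1, rpois(60, 120))
  counts <- dropletMultiome:::.sample_dm_matrix(totals, p, alpha = 30)
  mc <- multiome_counts(counts, Matrix::Matrix(0, 1, 60, sparse = TRUE))
  prof <- structure(list(modality = "RNA", proportions = p, alpha = 30),
                    class = "ambient_profile")
  pv_a <- mc_pvalues(mc, "RNA", prof, list(b = 10), mc_config(400, seed = 9))
  pv_b <- mc_pvalues(mc, "RNA", prof, list(b = 10), mc_config(400, seed = 9))
  pv_c <- mc_pvalues(mc, "RNA", prof, list(b = 10), mc_config(400, seed = 10))
  expect_identical(pv_a$p_values, pv_b$p_values)
  expect_false(identical(pv_a$p_values, pv_c$p_values))
})

test_that("power against a fixed signal grows with the droplet total", {
  set.seed(6)
  p <- as.numeric(sgt_oracle(rpois(150, 2) + rep(c(1, 0), c(40, 110))))
  signal <- sample(p)  # same weights on scrambled features
  meds <- vapply(c(100, 300, 1000), function(tt) {
    counts <- sapply(1:50, function(i) rmultinom(1, tt, signal))
    mc <- multiome_counts(Matrix::Matrix(counts, sparse = TRUE),
                          Matrix::Matrix(0, 1, 50, sparse = TRUE))
    prof <- structure(list(modality = "RNA", proportions = p, alpha = 50),
                      class = "ambient_profile")
    pv <- mc_pvalues(mc, "RNA", prof, list(b = 1), mc_config(500, seed = 2))
    median(pv$p_values[pv$tested])
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
})
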