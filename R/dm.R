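#' Dirichlet-multinomial log-likelihood of a count vector
#'
#' Log-likelihood of observing `counts` under the soup null: capture of soup
#' fragments is Dirichlet with concentration `alpha * proportions`, sequencing
#' is multinomial, and the compound is Dirichlet-multinomial
#' \deqn{L = \frac{t!\,\Gamma(\alpha)}{\Gamma(t+\alpha)}
#'   \prod_g \frac{\Gamma(x_g + \alpha p_g)}{x_g!\,\Gamma(\alpha p_g)}.}
#' Everything is evaluated through `lgamma` so large totals cannot overflow;
#' features with zero count contribute exactly 0.
#'
#' @param counts Non-negative integer vector.
#' @param proportions Per-feature probabilities summing to 1 (same length as
#'   `counts`).
#' @param alpha Positive over-dispersion scalar (smaller alpha = more
#'   variable droplet compositions).
#' @return The log-likelihood. If some feature has zero proportion but a
#'   positive count the likelihood is zero and `-Inf` is returned (this is a
#'   documented value, not an error).
#' @export
dm_log_likelihood <- function(counts, proportions, alpha) {
  if (length(counts) != length(proportions)) {
    stop("counts and proportions must have the same length", call. = FALSE)
  }
  if (anyNA(counts) || anyNA(proportions) || is.na(alpha)) {
    stop("NaN/NA inputs are not allowed", call. = FALSE)
  }
  stopifnot(alpha > 0, all(counts >= 0), all(counts == round(counts)),
            all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-6) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  nz <- counts > 0
  if (any(proportions[nz] == 0)) return(-Inf)
  t_tot <- sum(counts)
  ap <- alpha * proportions[nz]
  x <- counts[nz]
  lgamma(t_tot + 1) + lgamma(alpha) - lgamma(t_tot + alpha) +
    sum(lgamma(x + ap) - lgamma(x + 1) - lgamma(ap))
}

# Column-wise DM log-likelihood over a sparse feature x droplet matrix.
# Zero-proportion features with positive counts yield -Inf naturally via
# lgamma(0) = Inf.
.dm_loglik_columns <- function(mat, proportions, alpha) {
  t_tot <- as.numeric(Matrix::colSums(mat))
  nc <- ncol(mat)
  if (nc == 0L) return(numeric(0))
  x <- mat@x
  i <- mat@i + 1L
  j <- rep.int(seq_len(nc), diff(mat@p))
  ap <- alpha * proportions
  term <- lgamma(x + ap[i]) - lgamma(x + 1) - lgamma(ap[i])
  percol <- numeric(nc)
  if (length(term)) {
    agg <- rowsum(term, j)
    percol[as.integer(rownames(agg))] <- agg[, 1L]
  }
  lgamma(t_tot + 1) + lgamma(alpha) - lgamma(t_tot + alpha) + percol
}

# Total DM log-likelihood of a set of droplets as a function of alpha,
# computed from sparse triplets (x = values, i = feature index, t = per-droplet
# totals). Used by the alpha MLE.
.dm_loglik_total <- function(x, i, t_tot, proportions, alpha) {
  ap <- alpha * proportions
  sum(lgamma(t_tot + 1)) +
    length(t_tot) * lgamma(alpha) - sum(lgamma(t_tot + alpha)) +
    sum(lgamma(x + ap[i]) - lgamma(x + 1) - lgamma(ap[i]))
}

#' Maximum-likelihood estimate of the over-dispersion alpha
#'
#' Maximizes the summed Dirichlet-multinomial log-likelihood of the soup
#' droplets over alpha, on the log-alpha scale: a 30-point coarse grid over
#' `bounds` followed by golden-section/parabolic refinement
#' ([stats::optimize()]) to a relative tolerance of 1e-4.
#'
#' @param soup_counts Sparse feature x droplet matrix of soup-droplet counts,
#'   or a list of per-feature count vectors.
#' @param proportions Soup proportions (sum to 1).
#' @param bounds Positive search interval, default `c(0.01, 1e4)`.
#' @param max_droplets Cap on the number of droplets used (randomly sampled,
#'   seeded) to bound the MLE cost on large soups.
#' @param seed Seed for the droplet subsample.
#' @return The alpha estimate. If the likelihood is monotone up to a bound the
#'   bound is returned with a warning (near-multinomial or near-degenerate
#'   data).
#' @export
estimate_alpha <- function(soup_counts, proportions, bounds = c(0.01, 1e4),
                           max_droplets = 2000L, seed = 1L) {
  stopifnot(length(bounds) == 2L, all(bounds > 0), bounds[1] < bounds[2])
  if (is.list(soup_counts) && !is(soup_counts, "Matrix")) {
    soup_counts <- do.call(cbind, soup_counts)
    soup_counts <- as(as(as.matrix(soup_counts), "dMatrix"), "CsparseMatrix")
  }
  soup_counts <- as(soup_counts, "generalMatrix")
  keep <- which(Matrix::colSums(soup_counts) > 0)
  if (length(keep) < 2L) {
    stop("need at least 2 soup droplets with positive totals", call. = FALSE)
  }
  if (length(keep) > max_droplets) {
    set.seed(seed)
    keep <- sort(sample(keep, max_droplets))
  }
  mat <- soup_counts[, keep, drop = FALSE]
  x <- mat@x
  i <- mat@i + 1L
  t_tot <- as.numeric(Matrix::colSums(mat))

  f <- function(log_a) .dm_loglik_total(x, i, t_tot, proportions, exp(log_a))
  grid <- seq(log(bounds[1]), log(bounds[2]), length.out = 30L)
  vals <- vapply(grid, f, numeric(1))
  k <- which.max(vals)
  if (k == 1L || k == length(grid)) {
    warning("alpha likelihood is monotone up to the ",
            if (k == 1L) "lower" else "upper",
            " bound (", bounds[if (k == 1L) 1 else 2],
            "); data are near-", if (k == 1L) "degenerate" else "multinomial",
            call. = FALSE)
    return(bounds[if (k == 1L) 1 else 2])
  }
  opt <- optimize(f, interval = c(grid[k - 1L], grid[k + 1L]),
                  maximum = TRUE, tol = 1e-4)
  alpha <- exp(opt$maximum)
  # optimizer contract: never return something worse than the best grid point
  if (opt$objective < vals[k]) alpha <- exp(grid[k])
  alpha
}

#' Draw one Dirichlet-multinomial count vector
#'
#' Draws `theta ~ Dirichlet(alpha * proportions)` then
#' `counts ~ Multinomial(total, theta)`.
#'
#' @param total Non-negative integer total.
#' @param proportions Per-feature probabilities.
#' @param alpha Positive concentration scalar.
#' @return Integer vector summing to `total`.
#' @export
sample_dm_counts <- function(total, proportions, alpha) {
  stopifnot(total >= 0, alpha > 0)
  n <- length(proportions)
  if (total == 0) return(integer(n))
  theta <- rgamma(n, shape = alpha * proportions)
  if (sum(theta) <= 0) theta <- proportions  # all-underflow guard
  as.integer(rmultinom(1L, size = total, prob = theta))
}

#' Monte-Carlo configuration for the droplet test
#'
#' @param n_iters Number of Monte-Carlo iterations M (p-value resolution is
#'   `1/(M+1)`).
#' @param seed Integer seed.
#' @param log_tie_tol Tolerance for likelihood comparisons in log space; a
#'   simulated likelihood within `log_tie_tol` of the observed one counts as
#'   `<=` (ties are counted conservatively).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_iters = 10000L, seed = 1L, log_tie_tol = 1e-8) {
  stopifnot(n_iters >= 1, log_tie_tol >= 0)
  structure(list(n_iters = as.integer(n_iters), seed = as.integer(seed),
                 log_tie_tol = log_tie_tol), class = "mc_config")
}

#' Monte-Carlo p-values of one modality against the soup null
#'
#' Tests every droplet whose library size exceeds the technical-error
#' boundary `b` of the modality. For each tested droplet the observed
#' Dirichlet-multinomial log-likelihood under the soup profile is computed
#' once; `M` null count vectors are simulated at the same total and
#' `M_c` counts the iterations whose likelihood is less than or equal to the
#' observed one. The p-value is `(M_c + 1) / (M + 1)`. Droplets sharing a
#' total share the simulated null likelihoods; results are reproducible for a
#' fixed seed.
#'
#' @param mc A [multiome_counts()] object.
#' @param modality `"RNA"` or `"ATAC"`.
#' @param profile An [build_ambient_profile()] result with `alpha` set.
#' @param model The modality's [fit_library_size_model()] (or a list with
#'   `b`).
#' @param cfg A [mc_config()].
#' @return Object of class `modality_pvalues`: `tested` (named logical),
#'   `p_values` (named numeric, `NA` for untested barcodes), `m_c`,
#'   `n_iters`, `modality`.
#' @export
mc_pvalues <- function(mc, modality = c("RNA", "ATAC"), profile, model, cfg) {
  modality <- match.arg(modality)
  stopifnot(is(mc, "multiome_counts"), is(cfg, "mc_config"))
  if (is.na(profile$alpha)) {
    stop("profile$alpha is unset; run estimate_alpha() first", call. = FALSE)
  }
  mat <- if (modality == "RNA") mc$rna else mc$atac
  totals <- as.numeric(Matrix::colSums(mat))
  tested <- totals > model$b
  p <- rep(NA_real_, length(totals))
  m_c <- rep(NA_integer_, length(totals))
  names(p) <- names(m_c) <- names(tested) <- mc$barcodes
  if (!any(tested)) {
    warning("no ", modality, " droplets exceed b = ", signif(model$b, 4),
            "; nothing tested", call. = FALSE)
    return(structure(list(modality = modality, tested = tested,
                          p_values = p, m_c = m_c, n_iters = cfg$n_iters),
                     class = "modality_pvalues"))
  }

  idx <- which(tested)
  obs_ll <- .dm_loglik_columns(mat[, idx, drop = FALSE], profile$proportions,
                               profile$alpha)
  tt <- as.integer(round(totals[idx]))
  uniq <- sort(unique(tt))
  grp <- match(tt, uniq)
  ord <- order(grp)
  starts <- c(0L, cumsum(tabulate(grp, nbins = length(uniq))))

  set.seed(cfg$seed)
  m_sorted <- dm_mc_extreme_counts(
    prop = as.numeric(profile$proportions), alpha = profile$alpha,
    unique_totals = uniq, obs_loglik = obs_ll[ord],
    group_starts = starts, n_iters = cfg$n_iters, tie_tol = cfg$log_tie_tol
  )
  m_obs <- integer(length(idx))
  m_obs[ord] <- m_sorted
  m_c[idx] <- m_obs
  p[idx] <- (m_obs + 1) / (cfg$n_iters + 1)
  structure(list(modality = modality, tested = tested, p_values = p,
                 m_c = m_c, n_iters = cfg$n_iters),
            class = "modality_pvalues")
}

#' @export
print.modality_pvalues <- function(x, ...) {
  cat("modality_pvalues (", x$modality, "): ", sum(x$tested), " of ",
      length(x$tested), " barcodes tested at M = ", x$n_iters, "\n", sep = "")
  invisible(x)
}
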