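#' Fit the three-cluster library-size model of one modality
#'
#' Unfiltered droplet experiments show three clusters of library sizes per
#' modality: a technical-error cluster (barcodes with ~1 count arising from
#' chimeric molecules and uncorrected sequencing errors), an ambient cluster
#' (nuclei-free droplets that encapsulated soup), and the real nuclei. A
#' mixture of three Gaussians is fitted to log10 library sizes (totals below 1
#' are excluded) and two boundaries are derived on the count scale:
#'
#' * `b` — the end of the technical-error cluster: the library size at which a
#'   droplet is equally likely to be technical error or soup, i.e. where the
#'   weighted densities of the two lowest-mean components cross.
#' * `l` — the end of the ambient cluster: `l_sigmas` standard deviations
#'   above the ambient component mean (in log10 space), `10^(m2 + l_sigmas*s2)`.
#'
#' @param totals Numeric vector of per-barcode library sizes (one modality).
#' @param modality `"RNA"` or `"ATAC"`; sets the default `l_sigmas` (1.5 for
#'   RNA, 2 for ATAC).
#' @param l_sigmas Width of the ambient cluster in ambient-component standard
#'   deviations. `NULL` uses the per-modality default.
#' @param seed Integer seed (used only for jitter restarts if the initial fit
#'   fails; the default fit is deterministic).
#' @return An object of class `library_size_model` with elements `modality`,
#'   `weights`, `means`, `sds` (components sorted by increasing mean), `b`,
#'   `l`, `l_sigmas`, `n_used`.
#' @export
fit_library_size_model <- function(totals, modality = c("RNA", "ATAC"),
                                   l_sigmas = NULL, seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(l_sigmas)) l_sigmas <- if (modality == "RNA") 1.5 else 2.0
  stopifnot(is.numeric(l_sigmas), length(l_sigmas) == 1L, l_sigmas > 0)
  totals <- as.numeric(totals)
  lt <- log10(totals[is.finite(totals) & totals >= 1])
  if (length(unique(lt)) < 3L) {
    stop("need at least 3 distinct positive library sizes to fit the ",
         "mixture; supply manual b/l overrides instead", call. = FALSE)
  }

  fit <- .fit_gmm3(lt, seed = seed)
  if (is.null(fit)) {
    stop("Gaussian mixture fit failed after retries; supply manual b/l ",
         "overrides", call. = FALSE)
  }
  ord <- order(fit$mean)
  w <- fit$weight[ord]; mu <- fit$mean[ord]; sd3 <- fit$sd[ord]
  if (any(w <= 1e-8) || any(sd3 <= 0) || any(diff(mu) <= 0)) {
    stop("degenerate mixture fit (empty or coincident components); supply ",
         "manual b/l overrides", call. = FALSE)
  }

  log_b <- .density_crossing(w[1], mu[1], sd3[1], w[2], mu[2], sd3[2])
  if (is.na(log_b)) {
    stop("no density crossing between the technical-error and ambient ",
         "components (degenerate mixture)", call. = FALSE)
  }
  b <- 10^log_b
  l <- 10^(mu[2] + l_sigmas * sd3[2])
  if (!(b > 0 && b < l)) {
    stop("boundary inversion (b >= l); the mixture fit is degenerate",
         call. = FALSE)
  }
  structure(
    list(modality = modality, weights = w, means = mu, sds = sd3,
         b = b, l = l, l_sigmas = l_sigmas, n_used = length(lt),
         loglik = fit$ll),
    class = "library_size_model"
  )
}

# EM for a univariate 3-component Gaussian mixture with unequal variances.
# Initializations tried (best converged likelihood wins): means at the
# 10th/50th/90th percentiles; k-means centers (finds a nuclei component that
# holds only a few percent of barcodes, which mid-range percentiles miss);
# and jittered percentile restarts. The sd floor (0.15 dex) reflects the
# discreteness of counts near 1: log10 totals of the technical-error cluster
# sit on atoms (0, 0.30, 0.48, ...) whose spread is ~0.15, and without the
# floor a component can collapse onto a single atom with unbounded density
# and hijack the fit. Returns NULL if no attempt yields a finite, converged
# likelihood.
.fit_gmm3 <- function(x, seed, max_iter = 500L, tol = 1e-8, sd_floor = 0.15) {
  n <- length(x)
  best <- NULL
  for (attempt in 0:5) {
    if (attempt == 1 && length(unique(x)) >= 4) {
      set.seed(seed)
      km <- tryCatch(kmeans(x, centers = 3L, nstart = 5L),
                     error = function(e) NULL)
      if (is.null(km)) next
      mu <- as.numeric(km$centers)
    } else {
      mu <- quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
      if (attempt > 1) {
        set.seed(seed + attempt)
        mu <- mu + rnorm(3, sd = 0.05 * max(diff(range(x)), 1e-3))
      }
    }
    mu <- sort(mu)
    if (any(diff(mu) < 1e-6)) mu <- mu + c(-1e-3, 0, 1e-3)
    sdv <- rep(max(sd(x) / 3, sd_floor), 3L)
    w <- rep(1 / 3, 3L)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(1:3, function(k) w[k] * dnorm(x, mu[k], sdv[k]),
                     numeric(n))
      rs <- rowSums(dens)
      if (any(rs <= 0) || any(!is.finite(rs))) break
      ll <- sum(log(rs))
      resp <- dens / rs
      nk <- colSums(resp)
      if (any(nk < 1e-8)) break
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sdv <- pmax(sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk),
                  sd_floor)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    if (converged && (is.null(best) || ll > best$ll)) {
      best <- list(weight = w, mean = mu, sd = sdv, ll = ll)
    }
  }
  best
}

# First crossing of the two weighted Gaussian densities between their means,
# located on a 10,000-point grid and refined by root finding to 1e-6 log10
# units. Closed forms only exist for equal variances, hence the grid.
.density_crossing <- function(w1, m1, s1, w2, m2, s2) {
  h <- function(x) {
    (log(w1) + dnorm(x, m1, s1, log = TRUE)) -
      (log(w2) + dnorm(x, m2, s2, log = TRUE))
  }
  grid <- seq(m1, m2, length.out = 10000L)
  hv <- h(grid)
  flip <- which(hv[-length(hv)] > 0 & hv[-1L] <= 0)
  if (!length(flip)) return(NA_real_)
  k <- flip[1L]
  uniroot(h, lower = grid[k], upper = grid[k + 1L], tol = 1e-6)$root
}

#' @export
print.library_size_model <- function(x, ...) {
  cat("library_size_model (", x$modality, "), fitted on ", x$n_used,
      " barcodes\n", sep = "")
  comp <- data.frame(cluster = c("technical", "ambient", "nuclei"),
                     weight = round(x$weights, 4),
                     mean_log10 = round(x$means, 3),
                     sd_log10 = round(x$sds, 3))
  print(comp, row.names = FALSE)
  cat(sprintf("  b = %.2f, l = %.2f (counts; l = %.1f sigmas past ambient mean)\n",
              x$b, x$l, x$l_sigmas))
  invisible(x)
}

#' Select the soup (ambient-cluster) droplets
#'
#' Barcodes whose library size lies in the closed interval `[b, l]` of the
#' fitted model. Only these droplets are pooled into the soup profile.
#'
#' @param totals Per-barcode library sizes of the model's modality.
#' @param model A [fit_library_size_model()] result (or any list with `b`,
#'   `l`).
#' @return Integer indices into `totals` (names preserved if present).
#' @export
soup_droplets <- function(totals, model) {
  idx <- which(totals >= model$b & totals <= model$l)
  if (!length(idx)) {
    stop("no droplets fall in the ambient interval [b, l] = [",
         signif(model$b, 4), ", ", signif(model$l, 4), "]", call. = FALSE)
  }
  idx
}

#' Build the ambient (soup) profile of one modality
#'
#' Sums the counts of the soup droplets per feature and converts the summed
#' counts into posterior expected proportions with Simple Good-Turing
#' smoothing (see [good_turing_proportions()]), so that every feature —
#' including features unseen in the soup — receives a positive proportion.
#'
#' @param mc A [multiome_counts()] object.
#' @param soup_set Barcode indices from [soup_droplets()] (non-empty).
#' @param modality `"RNA"` or `"ATAC"`.
#' @return An object of class `ambient_profile` with `modality`, `raw_counts`,
#'   `proportions` (sum to 1), `alpha` (`NA` until estimated) and
#'   `n_soup_droplets`.
#' @export
build_ambient_profile <- function(mc, soup_set, modality = c("RNA", "ATAC")) {
  modality <- match.arg(modality)
  stopifnot(is(mc, "multiome_counts"), length(soup_set) > 0)
  mat <- if (modality == "RNA") mc$rna else mc$atac
  raw <- as.numeric(Matrix::rowSums(mat[, soup_set, drop = FALSE]))
  if (sum(raw) <= 0) {
    stop("soup droplets carry no ", modality, " counts", call. = FALSE)
  }
  gt <- good_turing_proportions(raw)
  structure(
    list(modality = modality, raw_counts = setNames(raw, rownames(mat)),
         proportions = setNames(gt$proportions, rownames(mat)),
         good_turing_method = gt$method, p0 = gt$p0,
         alpha = NA_real_, n_soup_droplets = length(soup_set)),
    class = "ambient_profile"
  )
}

#' @export
print.ambient_profile <- function(x, ...) {
  cat("ambient_profile (", x$modality, "): ", length(x$proportions),
      " features from ", x$n_soup_droplets, " soup droplets\n", sep = "")
  cat("  total soup counts:", sum(x$raw_counts),
      "| unseen mass p0:", signif(x$p0, 3),
      "| alpha:", if (is.na(x$alpha)) "unset" else signif(x$alpha, 4), "\n")
  invisible(x)
}

#' Export / import an ambient profile
#'
#' The profile is written as a two-column TSV (`feature_id`, `proportion`)
#' with a JSON sidecar (`<file>.json`) holding `modality`, `alpha`, `p0` and
#' the soup-droplet count, so a profile can be reused across runs.
#'
#' @param profile An `ambient_profile`.
#' @param path Output TSV path.
#' @return Invisibly, `path` (for `write_ambient_profile`); an
#'   `ambient_profile` (for `read_ambient_profile`).
#' @export
write_ambient_profile <- function(profile, path) {
  stopifnot(is(profile, "ambient_profile"))
  write.table(
    data.frame(feature_id = names(profile$proportions),
               proportion = profile$proportions),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  meta <- list(modality = profile$modality, alpha = profile$alpha,
               p0 = profile$p0, n_soup_droplets = profile$n_soup_droplets,
               good_turing_method = profile$good_turing_method)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ambient_profile
#' @param raw_counts Optional per-feature raw soup counts to attach on import.
#' @export
read_ambient_profile <- function(path, raw_counts = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(modality = meta$modality,
         raw_counts = raw_counts,
         proportions = setNames(tab$proportion, tab$feature_id),
         good_turing_method = meta$good_turing_method, p0 = meta$p0,
         alpha = if (is.null(meta$alpha)) NA_real_ else meta$alpha,
         n_soup_droplets = meta$n_soup_droplets),
    class = "ambient_profile"
  )
}
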