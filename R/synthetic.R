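#' Configuration for synthetic multiome datasets
#'
#' Describes a fully synthetic unfiltered multiome experiment with known
#' ground truth, mirroring the structure of real raw matrices: a
#' technical-error cluster of ~1-count barcodes, an ambient cluster of
#' nuclei-free droplets sharing one soup profile per modality, nuclei drawn
#' from several cell-type profiles, plus two perturbations — nuclei
#' downsampled and scrambled into a novel low-count cell type, and empty
#' droplets integer-amplified into a continuum of counts.
#'
#' Defaults place the ambient RNA cluster at a mode of ~90 counts and the
#' ambient ATAC cluster lower and closer to the technical cluster; nuclei
#' library sizes are log-normal around 10^4 (RNA) and 10^4.3 (ATAC) with
#' 0.2 dex spread, typical of droplet multiome libraries. Soup and cell-type profiles are sparse Dirichlet draws;
#' each cell type mixes the soup with its own profile so cells share
#' background expression with the ambient pool.
#'
#' @param n_genes,n_regions Feature-space sizes.
#' @param n_technical,n_ambient Numbers of technical-error and ambient
#'   (empty) barcodes.
#' @param g1 Number of untouched nuclei.
#' @param g2 Number of nuclei passed through downsampling + scrambling
#'   ("small" novel cell type).
#' @param n_amplified Number of integer-amplified empty droplets.
#' @param n_cell_types Number of distinct nucleus profiles.
#' @param soup_dirichlet Dirichlet sparsity of soup/cell profiles.
#' @param cell_profile_soup_weight Weight of the soup in each cell-type
#'   profile (0 = fully distinct cell types).
#' @param ambient_logmean_rna,ambient_logsd_rna,ambient_logmean_atac,ambient_logsd_atac
#'   Log10 location/spread of ambient library sizes.
#' @param nuclei_logmean_rna,nuclei_logsd_rna,nuclei_logmean_atac,nuclei_logsd_atac
#'   Log10 location/spread of nucleus library sizes.
#' @param alpha_rna,alpha_atac True over-dispersion of the soup draws.
#' @param downsample_frac_rna,downsample_frac_atac Binomial thinning rates for
#'   the g2 nuclei (defaults 0.20/0.20).
#' @param scramble_frac Fraction of each g2 nucleus' nonzero features whose
#'   identity is shuffled (default 0.10).
#' @param amp_range_rna,amp_range_atac Integer multiplier ranges for
#'   amplified empties (defaults `[2, 10]` RNA, `[2, 40]` ATAC).
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   configuration and this seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_regions = 2000L,
                       n_technical = 5000L, n_ambient = 5000L,
                       g1 = 500L, g2 = 200L, n_amplified = 300L,
                       n_cell_types = 5L, soup_dirichlet = 0.1,
                       cell_profile_soup_weight = 0.5,
                       ambient_logmean_rna = log10(90), ambient_logsd_rna = 0.25,
                       ambient_logmean_atac = 1.6, ambient_logsd_atac = 0.25,
                       nuclei_logmean_rna = 4.0, nuclei_logsd_rna = 0.2,
                       nuclei_logmean_atac = 4.3, nuclei_logsd_atac = 0.2,
                       alpha_rna = 100, alpha_atac = 50,
                       downsample_frac_rna = 0.2, downsample_frac_atac = 0.2,
                       scramble_frac = 0.1,
                       amp_range_rna = c(2L, 10L), amp_range_atac = c(2L, 40L),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_regions = as.integer(n_regions),
    n_technical = as.integer(n_technical), n_ambient = as.integer(n_ambient),
    g1 = as.integer(g1), g2 = as.integer(g2),
    n_amplified = as.integer(n_amplified),
    n_cell_types = as.integer(n_cell_types),
    soup_dirichlet = soup_dirichlet,
    cell_profile_soup_weight = cell_profile_soup_weight,
    ambient_logmean_rna = ambient_logmean_rna,
    ambient_logsd_rna = ambient_logsd_rna,
    ambient_logmean_atac = ambient_logmean_atac,
    ambient_logsd_atac = ambient_logsd_atac,
    nuclei_logmean_rna = nuclei_logmean_rna,
    nuclei_logsd_rna = nuclei_logsd_rna,
    nuclei_logmean_atac = nuclei_logmean_atac,
    nuclei_logsd_atac = nuclei_logsd_atac,
    alpha_rna = alpha_rna, alpha_atac = alpha_atac,
    downsample_frac_rna = downsample_frac_rna,
    downsample_frac_atac = downsample_frac_atac,
    scramble_frac = scramble_frac,
    amp_range_rna = as.integer(amp_range_rna),
    amp_range_atac = as.integer(amp_range_atac),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_genes >= 1, n_regions >= 1,
              n_technical >= 0, n_ambient >= 0, g1 >= 0, g2 >= 0,
              n_amplified >= 0, n_cell_types >= 1,
              soup_dirichlet > 0,
              cell_profile_soup_weight >= 0, cell_profile_soup_weight <= 1,
              alpha_rna > 0, alpha_atac > 0,
              downsample_frac_rna > 0, downsample_frac_rna <= 1,
              downsample_frac_atac > 0, downsample_frac_atac <= 1,
              scramble_frac >= 0, scramble_frac <= 1,
              length(amp_range_rna) == 2L, length(amp_range_atac) == 2L,
              amp_range_rna[1] >= 2L, amp_range_rna[1] <= amp_range_rna[2],
              amp_range_atac[1] >= 2L, amp_range_atac[1] <= amp_range_atac[2])
  })
  structure(cfg, class = "sim_config")
}

#' Tiny-cells simulation preset
#'
#' Variant in which 2000 of 4000 nuclei are downsampled to 6% of their RNA
#' and 2% of their ATAC library size without scrambling, placing a real cell
#' population below the k-means line of the assembled dataset.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_tiny_cells <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(g1 = 2000L, g2 = 2000L,
                   downsample_frac_rna = 0.06, downsample_frac_atac = 0.02,
                   scramble_frac = 0, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

.rdirichlet <- function(n, shape_scalar) {
  g <- rgamma(n, shape = shape_scalar)
  s <- sum(g)
  if (s <= 0) {
    g[] <- 0
    g[sample.int(n, 1L)] <- 1
    return(g)
  }
  g / s
}

# Dirichlet-multinomial draws for many droplets, chunked to bound memory.
# Returns a features x droplets dgCMatrix.
.sample_dm_matrix <- function(totals, proportions, alpha, chunk = 500L) {
  n_feat <- length(proportions)
  n <- length(totals)
  ii <- jj <- xx <- vector("list", ceiling(n / chunk))
  blk <- 0L
  ap <- alpha * proportions
  for (start in seq(1L, max(n, 1L), by = chunk)) {
    if (n == 0L) break
    end <- min(start + chunk - 1L, n)
    nb <- end - start + 1L
    theta <- matrix(rgamma(n_feat * nb, shape = ap), nrow = n_feat)
    cs <- colSums(theta)
    bad <- cs <= 0
    if (any(bad)) theta[, bad] <- proportions
    dense <- matrix(0L, nrow = n_feat, ncol = nb)
    for (c in seq_len(nb)) {
      tt <- totals[start + c - 1L]
      if (tt > 0) dense[, c] <- rmultinom(1L, size = tt, prob = theta[, c])
    }
    nz <- which(dense > 0L, arr.ind = TRUE)
    blk <- blk + 1L
    ii[[blk]] <- nz[, 1L]
    jj[[blk]] <- nz[, 2L] + start - 1L
    xx[[blk]] <- dense[nz]
  }
  .triplets_to_csparse(unlist(ii), unlist(jj), unlist(xx), n_feat, n)
}

.triplets_to_csparse <- function(i, j, x, nrow, ncol) {
  if (is.null(i)) i <- integer(0)
  if (is.null(j)) j <- integer(0)
  if (is.null(x)) x <- numeric(0)
  tm <- new("dgTMatrix", i = as.integer(i) - 1L, j = as.integer(j) - 1L,
            x = as.numeric(x), Dim = c(as.integer(nrow), as.integer(ncol)))
  as(tm, "CsparseMatrix")  # duplicated (i, j) triplets are summed here
}

#' Generate the base synthetic dataset
#'
#' Draws the soup profile of each modality once from a sparse Dirichlet, then
#' generates (in barcode order) the technical-error barcodes (~1-count totals
#' scattered over random features), the ambient/empty barcodes
#' (Dirichlet-multinomial draws from the soup with log-normal totals), and
#' `g1 + g2` nuclei (Dirichlet-multinomial draws from per-cell-type
#' profiles with larger totals). Fully determined by `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` ([multiome_counts()]), `truth` (data.frame
#'   `barcode`, `label`, `cell_type`), `soup_rna`, `soup_atac`,
#'   `profiles_rna`, `profiles_atac`, `config`.
#' @export
generate_base_dataset <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_nuc <- cfg$g1 + cfg$g2

  soup_rna <- .rdirichlet(cfg$n_genes, cfg$soup_dirichlet)
  soup_atac <- .rdirichlet(cfg$n_regions, cfg$soup_dirichlet)
  w <- cfg$cell_profile_soup_weight
  profiles_rna <- vapply(seq_len(cfg$n_cell_types), function(k) {
    w * soup_rna + (1 - w) * .rdirichlet(cfg$n_genes, cfg$soup_dirichlet)
  }, numeric(cfg$n_genes))
  profiles_atac <- vapply(seq_len(cfg$n_cell_types), function(k) {
    w * soup_atac + (1 - w) * .rdirichlet(cfg$n_regions, cfg$soup_dirichlet)
  }, numeric(cfg$n_regions))

  # technical-error barcodes: ~1 count on random features
  tech_rna <- .scatter_counts(pmax(1L, rpois(cfg$n_technical, 1)), cfg$n_genes)
  tech_atac <- .scatter_counts(pmax(1L, rpois(cfg$n_technical, 1)),
                               cfg$n_regions)

  amb_t_rna <- pmax(1, round(10^rnorm(cfg$n_ambient, cfg$ambient_logmean_rna,
                                      cfg$ambient_logsd_rna)))
  amb_t_atac <- pmax(1, round(10^rnorm(cfg$n_ambient, cfg$ambient_logmean_atac,
                                       cfg$ambient_logsd_atac)))
  amb_rna <- .sample_dm_matrix(amb_t_rna, soup_rna, cfg$alpha_rna)
  amb_atac <- .sample_dm_matrix(amb_t_atac, soup_atac, cfg$alpha_atac)

  cell_type <- if (n_nuc > 0) sample.int(cfg$n_cell_types, n_nuc, TRUE)
               else integer(0)
  nuc_t_rna <- pmax(1, round(10^rnorm(n_nuc, cfg$nuclei_logmean_rna,
                                      cfg$nuclei_logsd_rna)))
  nuc_t_atac <- pmax(1, round(10^rnorm(n_nuc, cfg$nuclei_logmean_atac,
                                       cfg$nuclei_logsd_atac)))
  nuc_rna <- .sample_dm_by_type(nuc_t_rna, profiles_rna, cell_type,
                                cfg$alpha_rna)
  nuc_atac <- .sample_dm_by_type(nuc_t_atac, profiles_atac, cell_type,
                                 cfg$alpha_atac)

  n_all <- cfg$n_technical + cfg$n_ambient + n_nuc
  barcodes <- sprintf("BC%06d-1", seq_len(n_all))
  rna <- cbind(tech_rna, amb_rna, nuc_rna)
  atac <- cbind(tech_atac, amb_atac, nuc_atac)
  mc <- multiome_counts(rna, atac, barcodes = barcodes,
                        gene_ids = sprintf("gene%05d", seq_len(cfg$n_genes)),
                        region_ids = sprintf("region%05d",
                                             seq_len(cfg$n_regions)))
  truth <- data.frame(
    barcode = barcodes,
    label = c(rep("technical", cfg$n_technical),
              rep("empty", cfg$n_ambient),
              rep("nucleus", n_nuc)),
    cell_type = c(rep(NA_integer_, cfg$n_technical + cfg$n_ambient),
                  cell_type),
    stringsAsFactors = FALSE
  )
  list(counts = mc, truth = truth, soup_rna = soup_rna, soup_atac = soup_atac,
       profiles_rna = profiles_rna, profiles_atac = profiles_atac,
       config = cfg)
}

# totals[j] unit counts assigned to uniformly random features of barcode j
.scatter_counts <- function(totals, n_feat) {
  totals <- as.integer(totals)
  n <- length(totals)
  tot <- sum(totals)
  i <- if (tot > 0) sample.int(n_feat, tot, replace = TRUE) else integer(0)
  j <- rep.int(seq_len(n), totals)
  .triplets_to_csparse(i, j, rep.int(1, tot), n_feat, n)
}

.sample_dm_by_type <- function(totals, profiles, cell_type, alpha) {
  n_feat <- nrow(profiles)
  n <- length(totals)
  out <- vector("list", max(ncol(profiles), 1L))
  ii <- jj <- xx <- list()
  for (k in seq_len(ncol(profiles))) {
    sel <- which(cell_type == k)
    if (!length(sel)) next
    m <- .sample_dm_matrix(totals[sel], profiles[, k], alpha)
    ii[[k]] <- m@i + 1L
    jj[[k]] <- sel[rep.int(seq_along(sel), diff(m@p))]
    xx[[k]] <- m@x
  }
  .triplets_to_csparse(unlist(ii), unlist(jj), unlist(xx), n_feat, n)
}

#' Downsample and scramble a set of barcodes
#'
#' Emulates a novel low-count cell type: every feature count of each selected
#' barcode is binomially thinned at the modality's rate (read-level
#' downsampling at count resolution), then a fraction `scramble_frac` of the
#' barcode's remaining nonzero features have their counts reassigned to
#' uniformly random feature indices (collisions summed). Totals after
#' scrambling equal totals after thinning by construction.
#'
#' @param mc A [multiome_counts()] object.
#' @param barcode_set Indices or names of barcodes to transform.
#' @param frac_rna,frac_atac Thinning rates in `(0, 1]`.
#' @param scramble_frac Fraction of nonzero features scrambled, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [multiome_counts()] with the selected columns replaced.
#' @export
downsample_and_scramble <- function(mc, barcode_set, frac_rna = 0.2,
                                    frac_atac = 0.2, scramble_frac = 0.1,
                                    seed = 1L) {
  stopifnot(is(mc, "multiome_counts"), length(barcode_set) > 0)
  if (is.character(barcode_set)) barcode_set <- match(barcode_set, mc$barcodes)
  stopifnot(!anyNA(barcode_set))
  set.seed(seed)
  rna <- .thin_scramble_columns(mc$rna, barcode_set, frac_rna, scramble_frac)
  atac <- .thin_scramble_columns(mc$atac, barcode_set, frac_atac,
                                 scramble_frac)
  multiome_counts(rna, atac, barcodes = mc$barcodes,
                  gene_ids = mc$gene_ids, region_ids = mc$region_ids)
}

.thin_scramble_columns <- function(mat, cols, frac, scramble_frac) {
  n_feat <- nrow(mat)
  p <- mat@p
  keep_cols <- setdiff(seq_len(ncol(mat)), cols)
  ii <- list(mat@i[.col_entry_idx(p, keep_cols)] + 1L)
  jj <- list(rep.int(keep_cols, p[keep_cols + 1L] - p[keep_cols]))
  xx <- list(mat@x[.col_entry_idx(p, keep_cols)])
  blk <- 1L
  for (cc in cols) {
    rng <- if (p[cc + 1L] > p[cc]) (p[cc] + 1L):p[cc + 1L] else integer(0)
    i <- mat@i[rng] + 1L
    x <- mat@x[rng]
    if (length(x)) {
      if (frac < 1) x <- rbinom(length(x), size = as.integer(x), prob = frac)
      nz <- x > 0
      i <- i[nz]; x <- x[nz]
      nnz <- length(i)
      ns <- round(scramble_frac * nnz)
      if (ns > 0) {
        pick <- sample.int(nnz, ns)
        i[pick] <- sample.int(n_feat, ns, replace = TRUE)
      }
    }
    blk <- blk + 1L
    ii[[blk]] <- i
    jj[[blk]] <- rep.int(cc, length(i))
    xx[[blk]] <- x
  }
  .triplets_to_csparse(unlist(ii), unlist(jj), unlist(xx), n_feat, ncol(mat))
}

.col_entry_idx <- function(p, cols) {
  if (!length(cols)) return(integer(0))
  unlist(lapply(cols, function(cc) {
    if (p[cc + 1L] > p[cc]) (p[cc] + 1L):p[cc + 1L] else integer(0)
  }))
}

#' Amplify empty droplets into a count continuum
#'
#' Creates `n_out` new barcodes, each a uniformly sampled source barcode whose
#' RNA vector is multiplied by an integer drawn uniformly from
#' `amp_range_rna` and whose ATAC vector by an independent integer from
#' `amp_range_atac`, producing a continuum of counts between empty droplets
#' and nuclei.
#'
#' @param mc A [multiome_counts()] object.
#' @param barcode_set Source barcodes (indices or names), typically the
#'   ambient cluster.
#' @param amp_range_rna,amp_range_atac Inclusive integer multiplier ranges
#'   (lower bounds >= 2).
#' @param n_out Number of amplified barcodes to create.
#' @param seed Integer seed.
#' @return A [multiome_counts()] holding only the new barcodes
#'   (`AMP000001...`), with attribute `amplification`: a data.frame of
#'   `barcode`, `source`, `k_rna`, `k_atac`.
#' @export
amplify_empties <- function(mc, barcode_set, amp_range_rna = c(2L, 10L),
                            amp_range_atac = c(2L, 40L), n_out, seed = 1L) {
  stopifnot(is(mc, "multiome_counts"), length(barcode_set) > 0, n_out >= 1)
  if (is.character(barcode_set)) barcode_set <- match(barcode_set, mc$barcodes)
  stopifnot(!anyNA(barcode_set))
  set.seed(seed)
  src <- barcode_set[sample.int(length(barcode_set), n_out, replace = TRUE)]
  # sample.int avoids base sample()'s scalar expansion for 1-point ranges
  k_rna <- amp_range_rna[1] +
    sample.int(amp_range_rna[2] - amp_range_rna[1] + 1L, n_out,
               replace = TRUE) - 1L
  k_atac <- amp_range_atac[1] +
    sample.int(amp_range_atac[2] - amp_range_atac[1] + 1L, n_out,
               replace = TRUE) - 1L
  rna <- .scaled_columns(mc$rna, src, k_rna)
  atac <- .scaled_columns(mc$atac, src, k_atac)
  out <- multiome_counts(rna, atac,
                         barcodes = sprintf("AMP%06d", seq_len(n_out)),
                         gene_ids = mc$gene_ids, region_ids = mc$region_ids)
  attr(out, "amplification") <- data.frame(
    barcode = out$barcodes, source = mc$barcodes[src],
    k_rna = k_rna, k_atac = k_atac, stringsAsFactors = FALSE
  )
  out
}

.scaled_columns <- function(mat, src, k) {
  p <- mat@p
  ii <- jj <- xx <- vector("list", length(src))
  for (o in seq_along(src)) {
    cc <- src[o]
    rng <- if (p[cc + 1L] > p[cc]) (p[cc] + 1L):p[cc + 1L] else integer(0)
    ii[[o]] <- mat@i[rng] + 1L
    jj[[o]] <- rep.int(o, length(rng))
    xx[[o]] <- mat@x[rng] * k[o]
  }
  .triplets_to_csparse(unlist(ii), unlist(jj), unlist(xx), nrow(mat),
                       length(src))
}

#' Assemble the benchmark simulation from a base dataset
#'
#' Returns the union of (i) all technical and empty barcodes, (ii) `g1`
#' untouched nuclei, (iii) `g2` nuclei passed through
#' [downsample_and_scramble()] (relabeled `small_nucleus`), and (iv)
#' `n_amplified` amplified empties drawn from the ambient cluster.
#'
#' @param base A [generate_base_dataset()] result (its nuclei count must be at
#'   least `g1 + g2`).
#' @param cfg The [sim_config()] (defaults to `base$config`).
#' @return A list with `counts`, `truth` (`barcode`, `label`, `cell_type`),
#'   and `config`.
#' @export
assemble_simulation <- function(base, cfg = base$config) {
  mc <- base$counts
  truth <- base$truth
  nuc_idx <- which(truth$label == "nucleus")
  if (length(nuc_idx) < cfg$g1 + cfg$g2) {
    stop("base dataset holds ", length(nuc_idx), " nuclei but g1 + g2 = ",
         cfg$g1 + cfg$g2, call. = FALSE)
  }
  keep_idx <- nuc_idx[seq_len(cfg$g1)]
  small_idx <- nuc_idx[cfg$g1 + seq_len(cfg$g2)]

  if (length(small_idx)) {
    mc <- downsample_and_scramble(mc, small_idx,
                                  frac_rna = cfg$downsample_frac_rna,
                                  frac_atac = cfg$downsample_frac_atac,
                                  scramble_frac = cfg$scramble_frac,
                                  seed = cfg$seed + 1L)
    truth$label[small_idx] <- "small_nucleus"
  }

  amb_idx <- which(truth$label == "empty")
  parts_mc <- list(subset_barcodes(mc, c(which(truth$label %in%
                     c("technical", "empty")), keep_idx, small_idx)))
  parts_truth <- list(truth[c(which(truth$label %in% c("technical", "empty")),
                              keep_idx, small_idx), ])
  if (cfg$n_amplified > 0) {
    if (!length(amb_idx)) stop("no ambient barcodes to amplify", call. = FALSE)
    amp <- amplify_empties(mc, amb_idx, cfg$amp_range_rna, cfg$amp_range_atac,
                           n_out = cfg$n_amplified, seed = cfg$seed + 2L)
    parts_mc[[2]] <- amp
    parts_truth[[2]] <- data.frame(barcode = amp$barcodes,
                                   label = "amplified_empty",
                                   cell_type = NA_integer_,
                                   stringsAsFactors = FALSE)
  }
  rna <- do.call(cbind, lapply(parts_mc, `[[`, "rna"))
  atac <- do.call(cbind, lapply(parts_mc, `[[`, "atac"))
  barcodes <- unlist(lapply(parts_mc, `[[`, "barcodes"))
  out_truth <- do.call(rbind, parts_truth)
  rownames(out_truth) <- NULL
  list(
    counts = multiome_counts(rna, atac, barcodes = barcodes,
                             gene_ids = mc$gene_ids,
                             region_ids = mc$region_ids),
    truth = out_truth,
    config = cfg
  )
}

#' Generate an assembled benchmark dataset in one call
#'
#' @param cfg A [sim_config()].
#' @return See [assemble_simulation()].
#' @export
simulate_dataset <- function(cfg) {
  assemble_simulation(generate_base_dataset(cfg), cfg)
}

#' Write simulation ground truth and configuration
#'
#' @param sim An [assemble_simulation()] / [simulate_dataset()] result.
#' @param path Output directory; writes the multiome matrix layout plus
#'   `truth.tsv` and `sim_config.json`.
#' @return Invisibly, `path`.
#' @export
write_simulation <- function(sim, path) {
  write_multiome_dir(sim$counts, path)
  write.table(sim$truth, file.path(path, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), file.path(path,
                                                      "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
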