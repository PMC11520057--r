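#' Read a CellRanger-arc style raw feature-barcode matrix directory
#'
#' Reads the three-file layout `matrix.mtx[.gz]`, `barcodes.tsv[.gz]`,
#' `features.tsv[.gz]` and splits the rows into the two modalities using the
#' third (feature type) column of the features file. Matrix Market indices are
#' 1-based on disk; values must be integers. Feature order within each
#' modality and barcode order are preserved exactly as on disk.
#'
#' @param path Directory containing the three files.
#' @param gex_tag,atac_tag Feature-type strings identifying gene-expression
#'   and ATAC-peak rows. Every value in the type column must equal one of the
#'   two tags.
#' @return A [multiome_counts()] object.
#' @export
read_multiome_dir <- function(path, gex_tag = "Gene Expression",
                              atac_tag = "Peaks") {
  mtx_f <- .find_layout_file(path, "matrix.mtx")
  bc_f <- .find_layout_file(path, "barcodes.tsv")
  ft_f <- .find_layout_file(path, "features.tsv")

  header <- .read_lines_maybe_gz(mtx_f, n = 1L)
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", header)) {
    stop("not a coordinate MatrixMarket file: ", mtx_f, call. = FALSE)
  }
  if (grepl("\\breal\\b|\\bcomplex\\b", header)) {
    stop("matrix.mtx declares a non-integer field type; ",
         "count matrices must be integer-valued: ", mtx_f, call. = FALSE)
  }
  m <- .with_maybe_gz(mtx_f, Matrix::readMM)
  m <- .as_count_matrix(m, "matrix.mtx")

  barcodes <- .read_lines_maybe_gz(bc_f)
  feats <- .with_maybe_gz(ft_f, function(con) {
    read.delim(con, header = FALSE, sep = "\t", quote = "",
               colClasses = "character")
  })
  if (ncol(feats) < 3L) {
    stop("features file must have >= 3 columns (id, name, type): ", ft_f,
         call. = FALSE)
  }
  if (nrow(feats) != nrow(m)) {
    stop("features file has ", nrow(feats), " rows but matrix has ",
         nrow(m), call. = FALSE)
  }
  if (length(barcodes) != ncol(m)) {
    stop("barcodes file has ", length(barcodes), " entries but matrix has ",
         ncol(m), " columns", call. = FALSE)
  }
  type <- feats[[3L]]
  bad <- setdiff(unique(type), c(gex_tag, atac_tag))
  if (length(bad)) {
    stop("unknown feature type value(s): ",
         paste(sQuote(bad), collapse = ", "),
         "; expected ", sQuote(gex_tag), " or ", sQuote(atac_tag),
         call. = FALSE)
  }
  is_gex <- type == gex_tag
  multiome_counts(
    rna_counts = m[is_gex, , drop = FALSE],
    atac_counts = m[!is_gex, , drop = FALSE],
    barcodes = barcodes,
    gene_ids = feats[[1L]][is_gex],
    region_ids = feats[[1L]][!is_gex]
  )
}

#' Write a multiome_counts object as a raw matrix directory
#'
#' Emits the `matrix.mtx`/`barcodes.tsv`/`features.tsv` layout readable by
#' [read_multiome_dir()]. The Matrix Market header declares an `integer`
#' field, matching the count-matrix dialect. All barcodes are written, even
#' all-zero ones.
#'
#' @param mc A [multiome_counts()] object.
#' @param path Output directory (created if needed).
#' @param gzip Write `.gz`-compressed files.
#' @param gex_tag,atac_tag Feature-type strings written to the features file.
#' @return Invisibly, the output directory path.
#' @export
write_multiome_dir <- function(mc, path, gzip = FALSE,
                               gex_tag = "Gene Expression",
                               atac_tag = "Peaks") {
  stopifnot(is(mc, "multiome_counts"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  ext <- if (gzip) ".gz" else ""

  n_genes <- nrow(mc$rna)
  # stacked matrix: RNA rows first, then ATAC rows (CellRanger-arc layout)
  ri <- mc$rna@i + 1L
  rj <- rep.int(seq_len(ncol(mc$rna)), diff(mc$rna@p))
  ai <- mc$atac@i + 1L + n_genes
  aj <- rep.int(seq_len(ncol(mc$atac)), diff(mc$atac@p))
  i <- c(ri, ai)
  j <- c(rj, aj)
  x <- c(mc$rna@x, mc$atac@x)

  mtx_path <- file.path(path, paste0("matrix.mtx", ext))
  con <- if (gzip) gzfile(mtx_path, "wb") else file(mtx_path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(n_genes + nrow(mc$atac), length(mc$barcodes),
                     length(x))), con)
  if (length(x)) {
    write.table(data.frame(i = i, j = j, x = as.integer(round(x))), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE,
                sep = " ")
  }

  .write_lines_maybe_gz(mc$barcodes, file.path(path, paste0("barcodes.tsv",
                                                            ext)))
  ft <- data.frame(
    id = c(mc$gene_ids, mc$region_ids),
    name = c(mc$gene_ids, mc$region_ids),
    type = c(rep(gex_tag, n_genes), rep(atac_tag, nrow(mc$atac))),
    stringsAsFactors = FALSE
  )
  .write_lines_maybe_gz(paste(ft$id, ft$name, ft$type, sep = "\t"),
                        file.path(path, paste0("features.tsv", ext)))
  invisible(path)
}

.find_layout_file <- function(path, base) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  for (cand in file.path(path, c(base, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  stop("missing file: ", file.path(path, paste0(base, "[.gz]")), call. = FALSE)
}

.with_maybe_gz <- function(path, fun) {
  con <- gzfile(path, "r")  # gzfile reads plain files transparently
  on.exit(close(con), add = TRUE)
  fun(con)
}

.read_lines_maybe_gz <- function(path, n = -1L) {
  .with_maybe_gz(path, function(con) readLines(con, n = n))
}

.write_lines_maybe_gz <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
}
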