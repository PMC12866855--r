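#' Write a count matrix as a Matrix Market triplet
#'
#' Emits the common single-cell exchange layout into \code{dir}:
#' \code{matrix.mtx} (genes as rows), \code{genes.tsv} (one gene id per
#' line, with header) and \code{barcodes.tsv} (columns \code{barcode},
#' \code{condition}, \code{cluster}). All tables are tab-delimited UTF-8
#' with a header row.
#'
#' @param m a \code{\link{count_matrix}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_counts <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(m$counts, paths[1])
  write_tsv(data.frame(gene = rownames(m$counts)), paths[2])
  meta <- m$cell_meta
  write_tsv(data.frame(barcode = meta$cell, condition = meta$condition,
                       cluster = meta$cluster), paths[3])
  invisible(paths)
}

#' Read a count matrix (Matrix Market triplet or dense table)
#'
#' Accepts either a directory containing \code{matrix.mtx} +
#' \code{genes.tsv} + \code{barcodes.tsv} (genes as matrix rows, the
#' single-cell convention), or a dense counts table (TSV/CSV, genes in
#' rows with a header of cell ids) plus a cell metadata table with columns
#' \code{barcode}, \code{condition}, \code{cluster}. Dimension mismatches
#' between the matrix and its sidecar files, non-integer counts and
#' missing metadata columns are rejected with explicit errors.
#'
#' @param path MTX directory, or dense counts file.
#' @param meta_path metadata TSV (required for dense input).
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts <- function(path, meta_path = NULL) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes_f <- file.path(path, "genes.tsv")
    bc_f <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes_f, bc_f))
      if (!file.exists(f)) stop("missing file: ", f)
    counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- read_tsv(genes_f)
    bc <- read_tsv(bc_f)
    if (nrow(genes) != nrow(counts))
      stop("gene sidecar '", genes_f, "' has ", nrow(genes),
           " rows but '", mtx, "' has ", nrow(counts), " matrix rows")
    if (nrow(bc) != ncol(counts))
      stop("barcode sidecar '", bc_f, "' has ", nrow(bc),
           " rows but '", mtx, "' has ", ncol(counts), " matrix columns")
    need <- c("barcode", "condition", "cluster")
    miss <- setdiff(need, names(bc))
    if (length(miss))
      stop("barcodes file '", bc_f, "' is missing column(s): ",
           paste(miss, collapse = ", "))
    dimnames(counts) <- list(genes[[1]], bc$barcode)
    meta <- data.frame(cell = bc$barcode, condition = bc$condition,
                       cluster = bc$cluster)
  } else {
    if (is.null(meta_path))
      stop("dense input needs `meta_path` (barcode/condition/cluster TSV)")
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE)
    counts <- as.matrix(tab)
    bc <- read_tsv(meta_path)
    miss <- setdiff(c("barcode", "condition", "cluster"), names(bc))
    if (length(miss))
      stop("metadata file '", meta_path, "' is missing column(s): ",
           paste(miss, collapse = ", "))
    if (!setequal(bc$barcode, colnames(counts)))
      stop("metadata barcodes do not match the counts columns")
    meta <- data.frame(cell = bc$barcode, condition = bc$condition,
                       cluster = bc$cluster)
  }
  count_matrix(counts, meta)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited gene-set format: one set per line — name,
#' description, then member genes. CRLF and LF line endings are both
#' accepted.
#'
#' @param path GMT file.
#' @return Named list of gene vectors with attribute \code{"source"} (the
#'   description field of each set is kept in attribute
#'   \code{"descriptions"}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line(s) (need name, description, >=1 gene): ",
         paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2)
  attr(sets, "source") <- path
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene vectors.
#' @param path output file.
#' @param descriptions per-set description field (default the set name).
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(length(sets) == 0 || !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Tab-delimited with header columns \code{ligand} and \code{receptor}
#' (a \code{pair} column is added when absent).
#'
#' @param path TSV file.
#' @return data.frame with \code{ligand}, \code{receptor}, \code{pair}.
#' @export
read_lr_pairs <- function(path) {
  tab <- read_tsv(path)
  miss <- setdiff(c("ligand", "receptor"), names(tab))
  if (length(miss))
    stop("pair table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(tab$pair))
    tab$pair <- paste(tab$ligand, tab$receptor, sep = "-")
  tab
}

# tab-delimited I/O with stable column order, header, LF endings and no
# quoting/row names; readers tolerate CRLF
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, comment.char = "",
                    stringsAsFactors = FALSE)
}
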