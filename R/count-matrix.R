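#' Gene-by-cell count matrix with per-cell metadata
#'
#' The central container of the package: a sparse non-negative integer
#' matrix of raw counts (genes in rows, cells in columns) together with a
#' per-cell metadata table carrying the condition label (e.g. \code{"ON"} /
#' \code{"OFF"}), the cluster id, and the two QC metrics every downstream
#' stage keys on: the number of detected genes (raw count > 0) and the
#' mitochondrial count fraction.
#'
#' QC metrics are always recomputed from the counts, never trusted from the
#' caller, so the container invariants (\code{n_genes_detected} equals the
#' per-cell number of non-zero genes; \code{mito_fraction} equals
#' mitochondrial counts over total counts) hold by construction.
#'
#' @param counts matrix or \code{Matrix::sparseMatrix} of non-negative
#'   integer counts, genes x cells, with row and column names.
#' @param cell_meta data.frame with one row per cell, containing at least
#'   \code{cell}, \code{condition} and \code{cluster} columns; rows are
#'   matched to matrix columns by the \code{cell} column.
#' @param mito_genes character vector of mitochondrial gene identifiers, or
#'   \code{NULL} to flag genes by the mouse \code{"mt-"} name prefix.
#'
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (a \code{dgCMatrix}) and \code{cell_meta} (a data.frame
#'   with columns \code{cell}, \code{condition}, \code{cluster},
#'   \code{n_genes_detected}, \code{mito_fraction}).
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(c("Cd3d", "mt-Nd1", "Krt8"), paste0("c", 1:4)))
#' meta <- data.frame(cell = paste0("c", 1:4),
#'                    condition = c("ON", "ON", "OFF", "OFF"), cluster = "0")
#' cm <- count_matrix(m, meta)
#' cm$cell_meta$mito_fraction
#' @export
count_matrix <- function(counts, cell_meta, mito_genes = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene row names and cell column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell identifiers in `counts`")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("`counts` must contain non-negative integers")
  if (!is.data.frame(cell_meta))
    stop("`cell_meta` must be a data.frame")
  need <- c("cell", "condition", "cluster")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss))
    stop("`cell_meta` is missing column(s): ", paste(miss, collapse = ", "))
  if (!setequal(cell_meta$cell, colnames(counts)))
    stop("`cell_meta$cell` does not match the columns of `counts`")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell), , drop = FALSE]
  rownames(cell_meta) <- NULL
  cell_meta$condition <- as.character(cell_meta$condition)
  cell_meta$cluster <- as.character(cell_meta$cluster)

  if (is.null(mito_genes))
    mito_genes <- grep("^mt-", rownames(counts), ignore.case = TRUE, value = TRUE)
  qc <- cell_qc_metrics(counts, mito_genes)
  cell_meta$n_genes_detected <- qc$n_genes_detected
  cell_meta$mito_fraction <- qc$mito_fraction

  structure(list(counts = counts, cell_meta = cell_meta,
                 mito_genes = mito_genes),
            class = "count_matrix")
}

# per-cell detected-gene count and mitochondrial fraction (zero-total cells
# get mito_fraction 0; they are removed by QC on the detected-gene rule)
cell_qc_metrics <- function(counts, mito_genes) {
  n_det <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  mito <- intersect(mito_genes, rownames(counts))
  mito_tot <- if (length(mito)) Matrix::colSums(counts[mito, , drop = FALSE])
              else rep(0, ncol(counts))
  frac <- ifelse(tot > 0, mito_tot / tot, 0)
  list(n_genes_detected = as.integer(n_det), mito_fraction = as.numeric(frac))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$cell_meta$condition)),
                                   table(x$cell_meta$condition)),
                           collapse = ", "), "\n")
  cat("clusters:", length(unique(x$cell_meta$cluster)), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# shared argument checks
.check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("`", name, "` must be a probability in [0, 1]")
  invisible(p)
}
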