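#' Cell-level quality-control filter
#'
#' Removes low-quality cells using the two standard exclusion rules for
#' droplet single-cell data: cells with fewer than \code{min_genes}
#' detected genes (raw count > 0) or with a mitochondrial count fraction
#' above \code{max_mito} are discarded. The boundaries are inclusive on the
#' retained side — a cell with exactly \code{min_genes} detected genes, or
#' exactly \code{max_mito} mitochondrial fraction, is kept — matching the
#' usual "fewer than" / "more than" phrasing of the exclusion rules. The
#' filter is idempotent and leaves the gene axis untouched.
#'
#' @param m a \code{\link{count_matrix}}.
#' @param min_genes minimum detected genes (default 200).
#' @param max_mito maximum mitochondrial fraction (default 0.10).
#' @return The filtered \code{count_matrix}, with an attribute
#'   \code{"qc"}: a list with \code{n_input}, \code{n_retained},
#'   \code{removed_low_genes}, \code{removed_high_mito} (a cell failing
#'   both rules is counted under both).
#' @examples
#' sim <- simulate_counts(demo_sim_config(n_cells_per_condition = 150, seed = 1))
#' qc <- qc_filter(sim$matrix)
#' attr(qc, "qc")
#' @export
qc_filter <- function(m, min_genes = 200, max_mito = 0.10) {
  stopifnot(inherits(m, "count_matrix"))
  if (!is.finite(min_genes) || min_genes < 0)
    stop("`min_genes` must be finite and >= 0")
  .check_prob(max_mito, "max_mito")
  meta <- m$cell_meta
  if (!all(c("n_genes_detected", "mito_fraction") %in% names(meta)))
    stop("cell metadata is missing QC columns")
  low <- meta$n_genes_detected < min_genes
  high <- meta$mito_fraction > max_mito
  keep <- !low & !high
  if (!any(keep))
    warning("QC removed every cell")
  out <- m
  out$counts <- m$counts[, keep, drop = FALSE]
  out$cell_meta <- meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  attr(out, "qc") <- list(n_input = nrow(meta), n_retained = sum(keep),
                          removed_low_genes = sum(low),
                          removed_high_mito = sum(high),
                          min_genes = min_genes, max_mito = max_mito)
  out
}

#' Counts-per-million normalization
#'
#' Scales each cell's counts to counts per million: \code{cpm(g, c) =
#' count(g, c) / total(c) * 1e6}, so every cell column sums to 1e6. CPM is
#' the unit the ligand-receptor interaction score consumes.
#'
#' @param m a \code{\link{count_matrix}} (QC-filtered; all cells must have
#'   positive total counts).
#' @return An object of class \code{cpm_matrix}: list with \code{cpm} (a
#'   \code{dgCMatrix}, genes x cells) and the carried-over \code{cell_meta}.
#' @export
cpm_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0))
    stop(sum(tot == 0), " cell(s) have zero total counts; run qc_filter() first")
  cpm <- m$counts %*% Matrix::Diagonal(x = 1e6 / tot)
  dimnames(cpm) <- dimnames(m$counts)
  structure(list(cpm = methods::as(cpm, "CsparseMatrix"),
                 cell_meta = m$cell_meta),
            class = "cpm_matrix")
}

#' Per-cluster mean expression profiles
#'
#' Arithmetic mean of per-cell CPM within each cluster, zeros included
#' (i.e. the mean over all member cells, not over expressing cells), with
#' the member count per cluster. These cluster means are the quantities the
#' ligand-receptor score multiplies.
#'
#' @param x a \code{cpm_matrix} from \code{\link{cpm_normalize}}.
#' @param clusters per-cell cluster labels (default: the metadata column).
#' @return An object of class \code{cluster_profile}: list with
#'   \code{means} (dense genes x clusters matrix), \code{n_cells} (named
#'   integer vector) and \code{cell_type} (filled by
#'   \code{\link{annotate_clusters}}, \code{NA} until then).
#' @export
cluster_means <- function(x, clusters = NULL) {
  stopifnot(inherits(x, "cpm_matrix"))
  if (is.null(clusters)) clusters <- x$cell_meta$cluster
  if (length(clusters) != ncol(x$cpm))
    stop("`clusters` must give one label per cell")
  if (anyNA(clusters)) stop("every cell needs a cluster label")
  clusters <- as.character(clusters)
  lev <- unique(clusters)
  ind <- Matrix::sparseMatrix(i = seq_along(clusters),
                              j = match(clusters, lev),
                              x = 1, dims = c(length(clusters), length(lev)))
  n <- as.integer(Matrix::colSums(ind))
  means <- as.matrix(x$cpm %*% ind %*% Matrix::Diagonal(x = 1 / n))
  dimnames(means) <- list(rownames(x$cpm), lev)
  structure(list(means = means,
                 n_cells = stats::setNames(n, lev),
                 cell_type = stats::setNames(rep(NA_character_, length(lev)), lev)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("cluster_profile: %d genes x %d clusters\n",
              nrow(x$means), ncol(x$means)))
  df <- data.frame(cluster = names(x$n_cells), n_cells = x$n_cells,
                   cell_type = x$cell_type[names(x$n_cells)],
                   row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' Marker panel for mouse tumor-microenvironment cell types
#'
#' The curated marker genes used to assign cell types to clusters:
#' immune cells (Ptprc), macrophages (Csf1r, C1qa, Cd68, Ccr2), neutrophils
#' (S100a8, Cxcr2), T cells (Cd3d, Cd3e), vascular cells (Pecam1, Flt1),
#' dendritic cells (Xcr1, Cd209a), tumor cells (Krt8, Krt18, rtTA3 — the
#' tet-transactivator marking engineered tumor cells), cancer-associated
#' fibroblasts (Dcn, Col1a1, Acta2) and B cells (Cd79a, Cd19, Igkc).
#'
#' @return Named list mapping cell-type name to marker gene identifiers.
#' @export
default_marker_panel <- function() {
  list("immune cells" = "Ptprc",
       "macrophages" = c("Csf1r", "C1qa", "Cd68", "Ccr2"),
       "neutrophils" = c("S100a8", "Cxcr2"),
       "T cells" = c("Cd3d", "Cd3e"),
       "vascular cells" = c("Pecam1", "Flt1"),
       "dendritic cells" = c("Xcr1", "Cd209a"),
       "tumor cells" = c("Krt8", "Krt18", "rtTA3"),
       "CAFs" = c("Dcn", "Col1a1", "Acta2"),
       "B cells" = c("Cd79a", "Cd19", "Igkc"))
}

#' Marker-panel cell-type annotation of clusters
#'
#' Scores every cluster against every panel entry as the mean of
#' \code{log1p(mean CPM)} over the entry's marker genes, and assigns the
#' top-scoring cell type when it beats the runner-up by at least
#' \code{margin} (multiplicative); otherwise the cluster is labelled
#' \code{"ambiguous"} rather than silently guessed. An all-zero profile is
#' always ambiguous. Panel genes absent from the matrix are dropped with a
#' warning; a panel entry losing all its genes is removed.
#'
#' @param p a \code{cluster_profile} from \code{\link{cluster_means}}.
#' @param panel named list of marker genes per cell type
#'   (default \code{\link{default_marker_panel}}).
#' @param margin required top / runner-up score ratio (default 1.2).
#' @return The profile with \code{cell_type} filled in and a
#'   \code{"type_scores"} attribute (types x clusters score matrix).
#' @export
annotate_clusters <- function(p, panel = default_marker_panel(), margin = 1.2) {
  stopifnot(inherits(p, "cluster_profile"))
  if (!is.list(panel) || length(panel) == 0)
    stop("`panel` must be a non-empty named list of marker genes")
  genes <- rownames(p$means)
  panel <- lapply(panel, unique)
  missing <- setdiff(unlist(panel, use.names = FALSE), genes)
  if (length(missing)) {
    warning("panel gene(s) absent from matrix, dropped: ",
            paste(missing, collapse = ", "))
    panel <- lapply(panel, intersect, y = genes)
    panel <- panel[lengths(panel) > 0]
    if (length(panel) == 0) stop("no panel genes present in the matrix")
  }
  lg <- log1p(p$means)
  scores <- do.call(rbind, lapply(panel, function(g)
    colMeans(lg[g, , drop = FALSE])))
  assign_one <- function(s) {
    o <- order(s, decreasing = TRUE)
    top <- s[o[1]]
    second <- if (length(s) > 1) s[o[2]] else 0
    if (top > 0 && top >= margin * second) names(s)[o[1]] else "ambiguous"
  }
  p$cell_type <- apply(scores, 2, function(s)
    assign_one(stats::setNames(s, rownames(scores))))
  attr(p, "type_scores") <- scores
  p
}

#' One-vs-rest Wilcoxon marker genes per cluster
#'
#' For every cluster, each gene is tested cluster-vs-rest with a two-sided
#' Wilcoxon rank-sum test on \code{log1p(CPM)} (normal approximation with
#' tie and continuity correction — the behaviour of
#' \code{stats::wilcox.test(exact = FALSE, correct = TRUE)}, vectorised
#' across genes). A gene is reported as a marker when its BH-adjusted p
#' (within cluster, across genes) is below \code{alpha}, it is up-regulated
#' in the cluster, and \code{log2((mean_in + 1) / (mean_out + 1))} of the
#' CPM means is at least \code{min_log2fc}. Constant genes get p = 1 and
#' are never selected. The procedure is deterministic.
#'
#' @param x a \code{cpm_matrix}.
#' @param clusters per-cell cluster labels (default: metadata column).
#' @param min_log2fc minimum log2 fold change of pseudocounted CPM means
#'   (default 0.25).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame with columns \code{cluster}, \code{gene},
#'   \code{log2fc}, \code{p_value}, \code{q_value}, sorted within cluster
#'   by p; use \code{split(res$gene, res$cluster)} for plain marker sets.
#' @export
find_markers <- function(x, clusters = NULL, min_log2fc = 0.25, alpha = 0.05) {
  stopifnot(inherits(x, "cpm_matrix"))
  if (is.null(clusters)) clusters <- x$cell_meta$cluster
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(x$cpm))
    stop("`clusters` must give one label per cell")
  lev <- unique(clusters)
  if (length(lev) < 2) stop("need at least 2 clusters")
  if (any(table(clusters) < 3)) stop("every cluster needs at least 3 cells")

  mat <- as.matrix(x$cpm)
  lg <- log1p(mat)
  N <- ncol(lg)
  # ranks and tie terms are cluster-independent: compute once per gene
  ranks <- matrix(0, nrow(lg), N, dimnames = dimnames(lg))
  tie_term <- numeric(nrow(lg))
  for (g in seq_len(nrow(lg))) {
    r <- rank(lg[g, ])
    ranks[g, ] <- r
    tt <- tabulate(match(r, unique(r)))
    tie_term[g] <- sum(tt^3 - tt)
  }

  res <- lapply(lev, function(cl) {
    in_cl <- clusters == cl
    n1 <- sum(in_cl); n2 <- N - n1
    w <- rowSums(ranks[, in_cl, drop = FALSE]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- w - mu
    cc <- sign(z) * 0.5  # continuity correction toward the null
    p <- ifelse(sigma2 <= 0, 1,
                2 * stats::pnorm(-abs((z - cc) / sqrt(pmax(sigma2, 1e-300)))))
    p <- pmin(p, 1)
    mean_in <- rowMeans(mat[, in_cl, drop = FALSE])
    mean_out <- rowMeans(mat[, !in_cl, drop = FALSE])
    l2fc <- log2((mean_in + 1) / (mean_out + 1))
    q <- stats::p.adjust(p, method = "BH")
    sel <- q < alpha & l2fc >= min_log2fc & mean_in > mean_out
    out <- data.frame(cluster = cl, gene = rownames(lg)[sel],
                      log2fc = l2fc[sel], p_value = p[sel], q_value = q[sel],
                      row.names = NULL)
    out[order(out$p_value, -out$log2fc), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
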