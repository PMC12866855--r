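#' Cross-tabulate cell types against conditions
#'
#' Builds the cell-count table feeding the per-type Fisher exact tests:
#' one row per cell type (or subpopulation), one column per condition, with
#' the column totals recording how many cells each condition contributed.
#'
#' @param meta data.frame with one row per cell.
#' @param type_col name of the cell-type column (default
#'   \code{"cell_type"}).
#' @param condition_col name of the condition column (default
#'   \code{"condition"}).
#' @param conditions expected condition labels in display order; labels in
#'   the data outside this set raise an error. \code{NULL} (default) takes
#'   the observed labels in sorted order.
#' @return A \code{composition_table}: integer matrix (types x conditions)
#'   with attribute \code{"totals"}, the per-condition column totals.
#' @export
build_composition <- function(meta, type_col = "cell_type",
                              condition_col = "condition",
                              conditions = NULL) {
  if (!all(c(type_col, condition_col) %in% names(meta)))
    stop("`meta` must contain columns '", type_col, "' and '", condition_col, "'")
  cond <- as.character(meta[[condition_col]])
  type <- as.character(meta[[type_col]])
  if (anyNA(cond) || anyNA(type))
    stop("every cell needs a condition and a cell type")
  if (is.null(conditions)) {
    conditions <- sort(unique(cond))
  } else if (!all(cond %in% conditions)) {
    stop("unknown condition label(s): ",
         paste(setdiff(cond, conditions), collapse = ", "))
  }
  tab <- table(factor(type, levels = sort(unique(type))),
               factor(cond, levels = conditions))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  composition_table(m, totals = colSums(m))
}

#' Construct a composition table from counts
#'
#' Lower-level constructor used when the group counts are not a partition
#' of the column totals (e.g. overlapping T-cell subpopulations counted
#' against the whole parent population).
#'
#' @param counts integer matrix, groups x conditions.
#' @param totals per-condition totals the groups are tested against
#'   (default: column sums of \code{counts}).
#' @return A \code{composition_table}.
#' @export
composition_table <- function(counts, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(totals) != ncol(counts))
    stop("`totals` must give one total per condition column")
  if (any(counts > rep(totals, each = nrow(counts))))
    stop("a group count exceeds its condition total")
  structure(counts, totals = stats::setNames(as.integer(totals),
                                             colnames(counts)),
            class = c("composition_table", class(counts)))
}

#' Fisher exact enrichment of each group between two conditions
#'
#' For each row of the composition table a 2x2 contingency table
#' (in-group / out-of-group x condition 1 / condition 2) is tested with the
#' two-sided Fisher exact test (point-probability method: the p-value sums
#' the probabilities of all tables, at fixed margins, no more likely than
#' the observed one). P-values are BH-adjusted across groups.
#'
#' The reported odds ratio is the sample odds ratio
#' \code{(a/c) / (b/d)} for group membership in the first condition column
#' relative to the second, with the Haldane–Anscombe 0.5 correction applied
#' to all four cells when any is zero; swapping the condition columns maps
#' it to its reciprocal and leaves p unchanged. Degenerate tables with an
#' empty margin report p = 1 and a missing odds ratio.
#'
#' @param tab a \code{composition_table} with exactly two condition
#'   columns.
#' @param adjust multiple-testing method passed to
#'   \code{stats::p.adjust} (default \code{"BH"}; use \code{"none"} to
#'   disable).
#' @return data.frame with columns \code{group}, per-condition counts and
#'   totals, \code{odds_ratio}, \code{p_value}, \code{q_value}.
#' @examples
#' tab <- composition_table(rbind("T cells" = c(ON = 10, OFF = 30)),
#'                          totals = c(ON = 100, OFF = 100))
#' fet_enrichment(tab)
#' @export
fet_enrichment <- function(tab, adjust = "BH") {
  stopifnot(inherits(tab, "composition_table"))
  if (ncol(tab) != 2)
    stop("fet_enrichment needs exactly two condition columns")
  totals <- attr(tab, "totals")
  res <- lapply(rownames(tab), function(g) {
    a <- tab[g, 1]; b <- tab[g, 2]
    c_ <- totals[1] - a; d <- totals[2] - b
    m <- matrix(c(a, c_, b, d), 2, 2)
    degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
    if (degenerate) {
      p <- 1; or <- NA_real_
    } else {
      p <- stats::fisher.test(m)$p.value
      or <- if (any(m == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
            else (a * d) / (b * c_)
    }
    data.frame(group = g, count_1 = a, count_2 = b,
               total_1 = totals[1], total_2 = totals[2],
               odds_ratio = unname(or), p_value = unname(min(p, 1)),
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  cn <- colnames(tab)
  names(out)[match(c("count_1", "count_2", "total_1", "total_2"),
                   names(out))] <-
    c(paste0("count_", cn), paste0("total_", cn))
  out$q_value <- stats::p.adjust(out$p_value, method = adjust)
  out[order(out$p_value), , drop = FALSE]
}

#' Count marker-positive subpopulations within a parent population
#'
#' Within a parent population (a cell type or a set of clusters), counts
#' the cells positive for each predicate gene (raw count at or above
#' \code{threshold}) and for the conjunction of all predicates (e.g.
#' Cd8a+ cells, Cd69+ cells and Cd8a+Cd69+ double-positive T cells), per
#' condition. The returned table's totals are the parent population sizes,
#' so \code{\link{fet_enrichment}} tests each subpopulation against the
#' rest of the parent.
#'
#' @param m a \code{\link{count_matrix}}.
#' @param parent logical vector over cells, or character vector of cluster
#'   ids defining the parent population.
#' @param genes predicate genes (e.g. \code{c("Cd8a", "Cd69")}); each must
#'   exist in the matrix.
#' @param threshold positivity threshold on the raw count (default 1, the
#'   simplest dropout-robust rule).
#' @param conditions condition column order for the table (default:
#'   observed, sorted).
#' @return A \code{composition_table} with one row per single-gene
#'   subpopulation plus (for >= 2 genes) the double/multi-positive
#'   conjunction row.
#' @export
subpop_counts <- function(m, parent, genes, threshold = 1,
                          conditions = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  absent <- setdiff(genes, rownames(m$counts))
  if (length(absent))
    stop("predicate gene(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  if (is.logical(parent)) {
    if (length(parent) != ncol(m$counts))
      stop("logical `parent` must have one entry per cell")
    in_parent <- parent
  } else {
    in_parent <- m$cell_meta$cluster %in% as.character(parent)
  }
  if (!any(in_parent))
    stop("parent population is empty")
  cond <- m$cell_meta$condition[in_parent]
  if (is.null(conditions)) conditions <- sort(unique(cond))
  cond <- factor(cond, levels = conditions)
  sub <- m$counts[genes, in_parent, drop = FALSE]
  pos <- as.matrix(sub >= threshold)
  rows <- lapply(genes, function(g) pos[g, ])
  names(rows) <- paste0(genes, "+")
  if (length(genes) >= 2)
    rows[[paste(paste0(genes, "+"), collapse = "")]] <-
      apply(pos, 2, all)
  counts <- do.call(rbind, lapply(rows, function(flag)
    as.integer(table(cond[flag]))))
  colnames(counts) <- conditions
  composition_table(counts, totals = as.integer(table(cond)))
}
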