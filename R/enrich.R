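#' Hypergeometric upper-tail probability
#'
#' Exact over-representation probability \eqn{P(X \ge k)} for drawing
#' \eqn{n} genes from a universe of \eqn{N} genes of which \eqn{K} belong
#' to the pathway:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}}
#' equivalently \eqn{1 - F(k - 1)} of the hypergeometric CDF. Terms are
#' accumulated in log space (log-gamma binomials with a log-sum-exp
#' reduction), so the computation stays finite and in [0, 1] for
#' genome-scale universes (N of order 20,000). \code{k = 0} returns
#' exactly 1 (the empty-sum case).
#'
#' @param N background universe size.
#' @param K pathway size within the universe (\code{K <= N}).
#' @param n number of marker genes drawn (\code{n <= N}).
#' @param k overlap count (\code{0 <= k <= min(K, n)}).
#' @return The upper-tail probability, a number in [0, 1].
#' @examples
#' hypergeom_upper(10, 5, 5, 5) # 1 / choose(10, 5)
#' @export
hypergeom_upper <- function(N, K, n, k) {
  for (nm in c("N", "K", "n", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v != round(v))
      stop("`", nm, "` must be a single integer")
  }
  if (N < 0) stop("`N` must be non-negative")
  if (K < 0 || K > N) stop("`K` must satisfy 0 <= K <= N")
  if (n < 0 || n > N) stop("`n` must satisfy 0 <= n <= N")
  if (k < 0 || k > min(K, n)) stop("`k` must satisfy 0 <= k <= min(K, n)")
  if (k == 0) return(1)
  i <- k:min(K, n)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  p <- exp(m + log(sum(exp(log_terms - m))))
  min(max(p, 0), 1)
}

#' Pool small clusters before enrichment
#'
#' Clusters with fewer than \code{min_n} cells lack power for
#' over-representation testing; this merges them into pooled groups whose
#' marker sets are unioned and whose sizes are summed. By default every
#' small cluster joins a single pooled group named by its members (e.g.
#' \code{"9+11"}); a user-supplied \code{pooling} map (group name ->
#' cluster ids) overrides the grouping. The rule is strict: a cluster of
#' exactly \code{min_n} cells is not pooled.
#'
#' @param marker_sets named list, cluster -> marker gene vector.
#' @param cluster_sizes named integer vector of cluster cell counts; every
#'   marker-set cluster must have a size.
#' @param min_n pooling threshold (default 50).
#' @param pooling optional named list mapping pooled-group name to the
#'   cluster ids it absorbs; ids must be known clusters.
#' @return list with \code{marker_sets} (pooled) and \code{sizes}
#'   (pooled group sizes).
#' @export
pool_small_clusters <- function(marker_sets, cluster_sizes, min_n = 50,
                                pooling = NULL) {
  cl <- names(marker_sets)
  if (is.null(cl) || !all(cl %in% names(cluster_sizes)))
    stop("every marker-set cluster needs an entry in `cluster_sizes`")
  sizes <- cluster_sizes[cl]
  if (!is.null(pooling)) {
    unknown <- setdiff(unlist(pooling, use.names = FALSE), cl)
    if (length(unknown))
      stop("pooling map references unknown cluster(s): ",
           paste(unknown, collapse = ", "))
  } else {
    small <- cl[sizes < min_n]
    pooling <- if (length(small) >= 2)
      stats::setNames(list(small),
                      paste(sort_numeric(small), collapse = "+"))
      else list()
  }
  pooled_members <- unlist(pooling, use.names = FALSE)
  keep <- setdiff(cl, pooled_members)
  out_sets <- marker_sets[keep]
  out_sizes <- sizes[keep]
  for (grp in names(pooling)) {
    mem <- pooling[[grp]]
    out_sets[[grp]] <- sort(unique(unlist(marker_sets[mem], use.names = FALSE)))
    out_sizes[[grp]] <- sum(sizes[mem])
  }
  list(marker_sets = out_sets, sizes = out_sizes)
}

# numeric-aware sort for cluster ids like "9", "11"
sort_numeric <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  if (anyNA(n)) sort(x) else x[order(n)]
}

#' Hypergeometric pathway over-representation per cluster
#'
#' Tests each (cluster group, pathway) combination for over-representation
#' of the group's marker genes in the pathway, via
#' \code{\link{hypergeom_upper}}. Marker and pathway genes are first
#' intersected with a declared gene universe (so \eqn{(N, K, n, k)} stay
#' self-consistent; dropped markers are counted in the output attributes),
#' and \eqn{N} is either the stated background size — conventionally the
#' approx. 20,000 protein-coding genes of a mammalian genome — or the
#' observed universe size. P-values are BH-adjusted within each group
#' across pathways.
#'
#' @param marker_sets named list, group -> marker genes (e.g. from
#'   \code{\link{find_markers}} + \code{\link{pool_small_clusters}}).
#' @param collection named list, pathway -> gene vector (e.g.
#'   \code{\link{read_gmt}} or \code{\link{simulate_genesets}}).
#' @param universe character vector of genes defining the observed
#'   universe (typically the matrix's gene names).
#' @param background \code{"observed"} to set \eqn{N} to the universe
#'   size, or an integer \eqn{N \ge} the universe size (default 20000).
#' @param adjust p-adjustment method (default \code{"BH"}).
#' @return data.frame with columns \code{group}, \code{pathway}, \code{N},
#'   \code{K}, \code{n}, \code{k}, \code{p_value}, \code{q_value}, sorted
#'   by q then p within group.
#' @export
enrich_pathways <- function(marker_sets, collection, universe,
                            background = 20000, adjust = "BH") {
  if (!length(marker_sets) || is.null(names(marker_sets)))
    stop("`marker_sets` must be a non-empty named list")
  if (!length(collection) || is.null(names(collection)))
    stop("`collection` must be a non-empty named list")
  universe <- unique(universe)
  N <- if (identical(background, "observed")) length(universe)
       else {
         if (!is.numeric(background) || background < length(universe))
           stop("`background` must be \"observed\" or an integer >= |universe| (",
                length(universe), ")")
         as.integer(background)
       }
  sets <- lapply(collection, function(g) unique(intersect(g, universe)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    warning("pathway(s) with no genes in the universe skipped: ",
            paste(empty, collapse = ", "))
    sets <- sets[lengths(sets) > 0]
  }
  if (!length(sets)) stop("no pathway overlaps the universe")

  res <- lapply(names(marker_sets), function(grp) {
    markers_all <- unique(marker_sets[[grp]])
    markers <- intersect(markers_all, universe)
    rows <- lapply(names(sets), function(pw) {
      K <- length(sets[[pw]])
      k <- length(intersect(markers, sets[[pw]]))
      data.frame(group = grp, pathway = pw, N = N, K = K,
                 n = length(markers), k = k,
                 p_value = hypergeom_upper(N, K, length(markers), k),
                 row.names = NULL)
    })
    out <- do.call(rbind, rows)
    out$q_value <- stats::p.adjust(out$p_value, method = adjust)
    out$n_markers_dropped <- length(markers_all) - length(markers)
    out[order(out$q_value, out$p_value, out$pathway), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise enrichment results as bar-plot coordinates
#'
#' Prepares the conventional horizontal-bar display of per-cluster
#' enrichment: bar length is the overlap count \code{k} and intensity is
#' \code{-log10(p)}. Plotting itself is left to the caller (a
#' \code{barplot(k, col = ...)} one-liner); this keeps the package free of
#' graphics dependencies.
#'
#' @param enr output of \code{\link{enrich_pathways}}.
#' @param max_per_group top pathways kept per group by q (default 10).
#' @return data.frame with \code{group}, \code{pathway}, \code{k},
#'   \code{neg_log10_p}, \code{q_value}.
#' @export
enrichment_bars <- function(enr, max_per_group = 10) {
  stopifnot(all(c("group", "pathway", "k", "p_value", "q_value") %in% names(enr)))
  parts <- lapply(split(enr, enr$group), function(d) {
    d <- d[order(d$q_value, d$p_value), , drop = FALSE]
    utils::head(d, max_per_group)
  })
  out <- do.call(rbind, parts)
  data.frame(group = out$group, pathway = out$pathway, k = out$k,
             neg_log10_p = -log10(pmax(out$p_value, .Machine$double.xmin)),
             q_value = out$q_value, row.names = NULL)
}
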