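# fixtures and independent oracles shared across test files

# small hand-built simulation config: 3 clusters, planted markers in "A",
# planted ligand Lg (sender "C") -> receptor Rc (receiver "A")
tiny_config <- function(n_cells = 300, seed = 11, dropout = 0.1,
                        t_on = 1 / 3, t_off = 1 / 3, lr_fc = c(ON = 1, OFF = 8)) {
  genes <- c("MkA1", "MkA2", "MkB1", "Lg", "Rc", "mt-G1",
             sprintf("G%03d", 1:54))
  bm <- stats::setNames(c(0.5, 0.5, 0.5, 0.4, 0.4, 3, rep(1, 54)), genes)
  props <- function(t) stats::setNames(c(t, (1 - t) * 0.6, (1 - t) * 0.4),
                                       c("A", "B", "C"))
  sim_config(
    n_cells_per_condition = n_cells,
    cluster_proportions = list(ON = props(t_on), OFF = props(t_off)),
    baseline_mean = bm,
    dispersion = 0.6,
    marker_effects = data.frame(
      cluster = c("A", "A", "B"), gene = c("MkA1", "MkA2", "MkB1"),
      fc = 25, condition = NA_character_),
    lr_effect = list(ligand = "Lg", receptor = "Rc", sender = "C",
                     receiver = "A", fc = lr_fc),
    mito_genes = "mt-G1",
    dropout_rate = dropout,
    cluster_types = c(A = "alpha", B = "beta", C = "gamma"),
    seed = seed)
}

# count_matrix built from an explicit dense matrix
toy_counts <- function(mat, condition = NULL, cluster = NULL) {
  if (is.null(condition)) condition <- rep("ON", ncol(mat))
  if (is.null(cluster)) cluster <- rep("0", ncol(mat))
  count_matrix(mat, data.frame(cell = colnames(mat), condition = condition,
                               cluster = cluster))
}

# cluster_profile built directly from a mean-CPM matrix
toy_profile <- function(means, n_cells = NULL) {
  if (is.null(n_cells))
    n_cells <- stats::setNames(rep(10L, ncol(means)), colnames(means))
  structure(list(means = means, n_cells = n_cells,
                 cell_type = stats::setNames(rep(NA_character_, ncol(means)),
                                             colnames(means))),
            class = "cluster_profile")
}

# hypergeometric upper tail by exact binomial-coefficient sums; choose() is
# exact in doubles for N <= 30, so this is an exact enumeration oracle
hyper_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hypergeometric upper tail by literal enumeration of every n-subset of a
# universe whose first K elements are the pathway (tiny N only)
hyper_subsets <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subs <- utils::combn(N, n)
  mean(colSums(subs <= K) >= k)
}

# two-sided Fisher p by fixed-margin enumeration with the point-probability
# rule (tables no more likely than observed, relative tolerance 1e-7)
fet_oracle <- function(a, b, c_, d) {
  m <- a + c_; n2 <- b + d; k <- a + b
  if (m + n2 == 0 || k == 0 || k == m + n2 || m == 0 || n2 == 0) return(1)
  x <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[x == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

# naive per-gene / per-cluster mean loop
means_oracle <- function(cpm, clusters) {
  lev <- unique(clusters)
  out <- matrix(NA_real_, nrow(cpm), length(lev),
                dimnames = list(rownames(cpm), lev))
  for (cl in lev)
    for (g in seq_len(nrow(cpm)))
      out[g, cl] <- mean(cpm[g, clusters == cl])
  out
}

# naive double-loop ligand-receptor scores
lr_oracle <- function(profiles, pairs, detect_cpm = 0.1) {
  rows <- list()
  for (cond in names(profiles)) {
    means <- profiles[[cond]]$means
    for (i in seq_len(nrow(pairs)))
      for (s in colnames(means))
        for (r in colnames(means)) {
          ml <- means[pairs$ligand[i], s]
          mr <- means[pairs$receptor[i], r]
          det <- ml > detect_cpm && mr > detect_cpm
          rows[[length(rows) + 1L]] <- data.frame(
            pair = paste(pairs$ligand[i], pairs$receptor[i], sep = "-"),
            sender = s, receiver = r, condition = cond,
            score = if (det) ml * mr else 0)
        }
  }
  do.call(rbind, rows)
}
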