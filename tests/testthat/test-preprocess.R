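test_that("QC applies the detected-gene and mitochondrial rules with inclusive boundaries", {
  # 4 cells: 150 genes (out), exactly 200 genes (in), high-mito (out),
  # exactly 10% mito (in)
  n_genes <- 260
  genes <- c(sprintf("g%03d", 1:(n_genes - 1)), "mt-X")
  mk_cell <- function(n_det, mito) {
    v <- numeric(n_genes)
    v[seq_len(n_det - (mito > 0))] <- 1
    v[n_genes] <- mito
    v
  }
  # cell4: 9 ordinary counts + 1 mito count = exactly 10% mito, 10 genes...
  # give it 200+ genes so only the mito rule is at stake
  m <- cbind(c1 = mk_cell(150, 0), c2 = mk_cell(200, 0),
             c3 = mk_cell(220, 30), c4 = c(rep(1, 225), numeric(n_genes - 226), 25))
  rownames(m) <- genes
  cm <- toy_counts(m)
  expect_equal(cm$cell_meta$n_genes_detected, c(150, 200, 220, 226))
  expect_equal(cm$cell_meta$mito_fraction[3], 30 / 249)
  expect_equal(cm$cell_meta$mito_fraction[4], 0.10)

  qc <- qc_filter(cm)
  expect_setequal(qc$cell_meta$cell, c("c2", "c4"))
  rep <- attr(qc, "qc")
  expect_equal(rep$removed_low_genes, 1)
  expect_equal(rep$removed_high_mito, 1)
  expect_equal(nrow(qc$counts), n_genes)  # gene axis untouched
})

test_that("QC is idempotent", {
  sim <- simulate_counts(demo_sim_config(n_cells_per_condition = 150, seed = 2))
  once <- qc_filter(sim$matrix)
  twice <- qc_filter(once)
  expect_identical(once$counts, twice$counts)
  expect_identical(once$cell_meta, twice$cell_meta)
  expect_lt(attr(once, "qc")$n_retained, attr(once, "qc")$n_input)
})

test_that("CPM normalization is definitional, sums to 1e6 and is scale invariant", {
  m <- matrix(c(1, 999, 5, 495), 2, 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  cm <- toy_counts(m)
  cpm <- cpm_normalize(cm)
  expect_equal(cpm$cpm["gA", "c1"], 1000)
  expect_equal(unname(Matrix::colSums(cpm$cpm)), c(1e6, 1e6))

  m2 <- m; m2[, 1] <- m2[, 1] * 2
  cpm2 <- cpm_normalize(toy_counts(m2))
  expect_equal(as.matrix(cpm$cpm), as.matrix(cpm2$cpm))

  m3 <- m; m3[, 2] <- 0
  expect_error(cpm_normalize(toy_counts(m3)), "qc_filter")
})

test_that("cluster means equal the naive per-gene loop and commute with reordering", {
  set.seed(42)
  m <- matrix(rpois(30 * 80, 3), 30, 80,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:80)))
  cl <- sample(c("x", "y", "z"), 80, replace = TRUE)
  cpm <- cpm_normalize(toy_counts(m, cluster = cl))
  prof <- cluster_means(cpm)
  oracle <- means_oracle(as.matrix(cpm$cpm), cl)
  expect_equal(prof$means[, colnames(oracle)], oracle, tolerance = 1e-12)

  perm <- sample(80)
  cpm_p <- cpm_normalize(toy_counts(m[, perm], cluster = cl[perm]))
  prof_p <- cluster_means(cpm_p)
  expect_equal(prof_p$means[, colnames(prof$means)], prof$means,
               tolerance = 1e-12)
  expect_equal(prof_p$n_cells[names(prof$n_cells)], prof$n_cells)

  # two cells with CPM 0 and 10 average to 5
  prof2 <- toy_profile(matrix(c(0, 10), 1, 2,
                              dimnames = list("g", c("a", "b"))))
  mm <- matrix(c(0, 10), nrow = 1, dimnames = list("g", c("c1", "c2")))
  cp <- structure(list(cpm = Matrix::Matrix(mm, sparse = TRUE),
                       cell_meta = data.frame(cell = c("c1", "c2"),
                                              condition = "ON",
                                              cluster = "k")),
                  class = "cpm_matrix")
  expect_equal(unname(cluster_means(cp)$means[1, 1]), 5)
})

test_that("marker-panel annotation assigns elevated panels and refuses ambiguity", {
  genes <- unique(unlist(default_marker_panel()))
  means <- matrix(5, length(genes), 2,
                  dimnames = list(genes, c("k1", "k2")))
  means[c("Cd3d", "Cd3e"), "k1"] <- 5000   # T-cell panel elevated in k1
  p <- annotate_clusters(toy_profile(means))
  expect_equal(unname(p$cell_type["k1"]), "T cells")
  expect_equal(unname(p$cell_type["k2"]), "ambiguous")

  zero <- toy_profile(matrix(0, length(genes), 1,
                             dimnames = list(genes, "k0")))
  expect_equal(unname(annotate_clusters(zero)$cell_type["k0"]), "ambiguous")

  expect_error(annotate_clusters(p, panel = list()), "non-empty")
})

test_that("annotation recovers planted cell types and ignores cluster relabeling", {
  sim <- simulate_counts(demo_sim_config(n_cells_per_condition = 400, seed = 6))
  cpm <- cpm_normalize(qc_filter(sim$matrix))
  prof <- annotate_clusters(cluster_means(cpm))
  truth_types <- sim$truth$cluster_types[names(prof$cell_type)]
  expect_gte(sum(prof$cell_type == truth_types), 14)

  relab <- paste0("cl_", cpm$cell_meta$cluster)
  prof2 <- annotate_clusters(cluster_means(cpm, clusters = relab))
  expect_equal(unname(prof2$cell_type[paste0("cl_", names(prof$cell_type))]),
               unname(prof$cell_type))
})

test_that("marker finder matches the rank-sum oracle on a toy matrix", {
  set.seed(7)
  n1 <- 14; n2 <- 26
  m <- matrix(rpois(20 * (n1 + n2), 4), 20, n1 + n2,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("c%02d", 1:(n1 + n2))))
  m[1:3, 1:n1] <- m[1:3, 1:n1] + rpois(3 * n1, 12)  # up in cluster one
  cl <- rep(c("one", "two"), c(n1, n2))
  cpm <- cpm_normalize(toy_counts(m, cluster = cl))
  res <- find_markers(cpm, min_log2fc = 0.25, alpha = 0.05)

  lg <- log1p(as.matrix(cpm$cpm))
  mat <- as.matrix(cpm$cpm)
  for (grp in c("one", "two")) {
    ps <- vapply(rownames(lg), function(g)
      stats::wilcox.test(lg[g, cl == grp], lg[g, cl != grp],
                         exact = FALSE, correct = TRUE)$p.value, 0)
    ps[is.nan(ps)] <- 1
    l2fc <- log2((rowMeans(mat[, cl == grp]) + 1) /
                 (rowMeans(mat[, cl != grp]) + 1))
    qs <- p.adjust(ps, "BH")
    sel <- names(ps)[qs < 0.05 & l2fc >= 0.25]
    got <- res$gene[res$cluster == grp]
    expect_setequal(got, sel)
    expect_equal(res$p_value[res$cluster == grp][order(got)],
                 unname(ps[sort(got)]), tolerance = 1e-9)
  }
})

test_that("maximal separation is selected, identical distributions are not", {
  # equalized library sizes so a flat gene is flat in CPM too: the
  # compensator absorbs the on/off gene's contribution to the totals
  n1 <- 50; n2 <- 500
  m <- rbind(on_gene = c(rep(100, n1), rep(0, n2)),
             comp = c(rep(0, n1), rep(100, n2)),
             flat = rep(7, n1 + n2),
             filler = rep(50, n1 + n2))
  colnames(m) <- sprintf("c%03d", seq_len(n1 + n2))
  cl <- rep(c("A", "rest"), c(n1, n2))
  res <- find_markers(cpm_normalize(toy_counts(m, cluster = cl)),
                      min_log2fc = 0.25)
  expect_true("on_gene" %in% res$gene[res$cluster == "A"])
  expect_false("flat" %in% res$gene)   # constant CPM: p = 1, never a marker
  expect_false("filler" %in% res$gene)
})

test_that("rank-sum p-values are invariant to a common CPM scale factor", {
  set.seed(9)
  m <- matrix(rpois(15 * 40, 5), 15, 40,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("c%02d", 1:40)))
  cl <- rep(c("A", "B"), 20)
  cpm <- cpm_normalize(toy_counts(m, cluster = cl))
  res1 <- find_markers(cpm, alpha = 1.1, min_log2fc = -Inf)
  scaled <- cpm
  scaled$cpm <- cpm$cpm * 1000
  res2 <- find_markers(scaled, alpha = 1.1, min_log2fc = -Inf)
  key <- function(d) d[order(d$cluster, d$gene), ]
  expect_equal(key(res1)$p_value, key(res2)$p_value, tolerance = 1e-12)
  expect_equal(sign(key(res1)$log2fc), sign(key(res2)$log2fc))
})
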