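test_that("config validation names the offending field", {
  cfg <- tiny_config()
  bad <- cfg$cluster_proportions
  bad$ON["A"] <- bad$ON["A"] + 0.05
  expect_error(sim_config(100, bad, cfg$baseline_mean),
               "cluster_proportions")
  expect_error(sim_config(0, cfg$cluster_proportions, cfg$baseline_mean),
               "n_cells_per_condition")
  bm <- cfg$baseline_mean; bm[1] <- -1
  expect_error(sim_config(100, cfg$cluster_proportions, bm),
               "baseline_mean")
  expect_error(sim_config(100, cfg$cluster_proportions, cfg$baseline_mean,
                          marker_effects = data.frame(cluster = "A",
                                                      gene = "MkA1",
                                                      fc = -2)),
               "marker_effects")
  expect_error(sim_config(100, cfg$cluster_proportions, cfg$baseline_mean,
                          dispersion = 0),
               "dispersion")
})

test_that("full dropout zeroes the matrix and labels still cover every cell", {
  cfg <- tiny_config(n_cells = 50, dropout = 1)
  sim <- simulate_counts(cfg)
  expect_equal(sum(sim$matrix$counts), 0)
  expect_equal(nrow(sim$truth$cells), ncol(sim$matrix$counts))
  expect_true(all(sim$truth$cells$cell == sim$matrix$cell_meta$cell))
})

test_that("identical config and seed give bit-identical output", {
  cfg <- tiny_config(n_cells = 120, seed = 99)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$matrix$cell_meta, b$matrix$cell_meta)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- simulate_counts(tiny_config(n_cells = 120, seed = 100))
  expect_false(identical(a$matrix$counts, c$matrix$counts))
})

test_that("without marker effects, per-gene means are homogeneous across clusters", {
  genes <- stats::setNames(rep(2, 40), sprintf("G%02d", 1:40))
  cfg <- sim_config(
    n_cells_per_condition = 2500,
    cluster_proportions = list(ON = c(A = 0.5, B = 0.5),
                               OFF = c(A = 0.5, B = 0.5)),
    baseline_mean = genes, dispersion = 0.5, dropout_rate = 0, seed = 3)
  sim <- simulate_counts(cfg)
  cl <- sim$matrix$cell_meta$cluster
  mA <- Matrix::rowMeans(sim$matrix$counts[, cl == "A"])
  mB <- Matrix::rowMeans(sim$matrix$counts[, cl == "B"])
  # NB sd per gene ~ sqrt(2 + 0.5*4) = 2; SE of a mean difference at
  # n ~ 2500/cluster is ~0.057 -> 4.5 SE bound
  expect_lt(max(abs(mA - mB)), 4.5 * sqrt(2 * (2 + 0.5 * 4) / 2400))
})

test_that("planted composition shift stays inside its binomial 99% envelope", {
  cfg <- tiny_config(n_cells = 2000, seed = 5, t_on = 0.05, t_off = 0.20)
  sim <- simulate_counts(cfg)
  tab <- table(sim$truth$cells$condition, sim$truth$cells$cluster)
  for (cond in c("ON", "OFF")) {
    p <- if (cond == "ON") 0.05 else 0.20
    lo <- qbinom(0.005, 2000, p); hi <- qbinom(0.995, 2000, p)
    expect_gte(tab[cond, "A"], lo)
    expect_lte(tab[cond, "A"], hi)
  }
})

test_that("counts match negative-binomial moments when dropout is off", {
  genes <- stats::setNames(c(1, 4, 10), c("g1", "g2", "g3"))
  alpha <- 0.7
  cfg <- sim_config(
    n_cells_per_condition = 1500,
    cluster_proportions = list(ON = c(A = 1), OFF = c(A = 1)),
    baseline_mean = genes, dispersion = alpha, dropout_rate = 0, seed = 8)
  sim <- simulate_counts(cfg)
  x <- as.matrix(sim$matrix$counts)
  n <- ncol(x)
  for (g in names(genes)) {
    mu <- genes[[g]]
    v <- mu + mu^2 * alpha
    se_mean <- sqrt(v / n)
    expect_lt(abs(mean(x[g, ]) - mu), 3 * se_mean)
    # SE of a sample variance ~ sqrt(2/n) * v for roughly NB tails; use a
    # generous 5x band to keep the check sharp but stable
    expect_lt(abs(var(x[g, ]) - v), 5 * sqrt(2 / n) * v)
  }
})

test_that("gene-set simulation plants the designated markers and is byte-stable", {
  sim <- simulate_counts(tiny_config(n_cells = 60))
  sets <- simulate_genesets(sim$truth, n_pathways = 12, sizes = 10, seed = 4,
                            designated_cluster = "A", overlap_fraction = 1)
  expect_true(all(sim$truth$markers[["A"]] %in% sets$planted_pathway))
  expect_length(sets, 12)
  expect_true(all(lengths(sets) == 10))

  expect_length(simulate_genesets(sim$truth, n_pathways = 0, seed = 4), 0)
  expect_error(simulate_genesets(sim$truth, n_pathways = 2, sizes = 1e5,
                                 seed = 4), "universe")

  f1 <- tempfile(fileext = ".gmt"); f2 <- tempfile(fileext = ".gmt")
  write_gmt(simulate_genesets(sim$truth, 12, 10, seed = 4,
                              designated_cluster = "A"), f1)
  write_gmt(simulate_genesets(sim$truth, 12, 10, seed = 4,
                              designated_cluster = "A"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("tumor series follows the piecewise growth-decay model", {
  model <- list(growth_rate = 0.3, regression_rate = 0, switch_day = 5,
                noise_sd = 0, seed = 1)
  s <- simulate_tumor_series(model, days = 0:5, n_subjects = 1)
  expect_equal(s$radiance, 100 * exp(0.3 * (0:5)), tolerance = 1e-12)

  # regression to 1% of peak by construction: rate = log(100) / 7
  model2 <- list(growth_rate = 0.3, regression_rate = log(100) / 7,
                 switch_day = 0, noise_sd = 0, seed = 1)
  s2 <- simulate_tumor_series(model2, days = c(0, 7), n_subjects = 1)
  rel <- relative_series(s2, baseline_day = 0)
  expect_equal(rel$relative[rel$day == 7], 0.01, tolerance = 1e-12)

  model3 <- list(growth_rate = 0.2, regression_rate = 0.5, switch_day = 4,
                 noise_sd = 0.2, seed = 77)
  expect_identical(simulate_tumor_series(model3, 0:8),
                   simulate_tumor_series(model3, 0:8))
  expect_error(simulate_tumor_series(model3, c(0, 2, 2, 3)),
               "strictly increasing")
})
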