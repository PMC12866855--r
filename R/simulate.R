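#' Configuration for the two-condition single-cell count simulator
#'
#' Builds and validates the parameter set consumed by
#' \code{\link{simulate_counts}}. The simulator draws gene-wise
#' negative-binomial counts (variance \eqn{\mu + \mu^2 \alpha}) whose means
#' are a per-gene baseline multiplied by cluster- (and optionally
#' condition-) specific fold changes, then thins every entry by independent
#' Bernoulli dropout. Cluster sizes are multinomial draws from per-condition
#' cluster proportion vectors, so condition-dependent composition shifts
#' (e.g. T-cell expansion after oncogene withdrawal) are planted through the
#' proportions, and crosstalk is planted through \code{lr_effect}, a
#' per-condition fold change applied to the ligand in its sender cluster and
#' the receptor in its receiver cluster.
#'
#' A fraction \code{low_quality_rate} of cells is simulated as damaged:
#' their non-mitochondrial means are shrunk by \code{low_quality_depth} and
#' their mitochondrial means inflated by \code{low_quality_mito}, producing
#' the low-detected-gene / high-mitochondrial-fraction tail that cell QC is
#' designed to remove.
#'
#' @param n_cells_per_condition cells to draw per condition (positive).
#' @param cluster_proportions named list, one probability vector per
#'   condition (same cluster names in the same order, each summing to 1).
#' @param baseline_mean named per-gene expected count (>= 0); names define
#'   the gene universe.
#' @param dispersion per-gene NB dispersion alpha > 0 (scalar recycled).
#' @param marker_effects data.frame with columns \code{cluster},
#'   \code{gene}, \code{fc} and optionally \code{condition} (NA = both
#'   conditions); multiplies the baseline mean in that cluster.
#' @param lr_effect \code{NULL}, or a list with \code{ligand},
#'   \code{receptor}, \code{sender}, \code{receiver} and \code{fc}, a named
#'   per-condition fold change vector.
#' @param mito_genes gene names treated as mitochondrial (default: the
#'   \code{"mt-"} prefix convention of mouse nomenclature).
#' @param dropout_rate probability in [0,1] of zeroing any count entry.
#' @param low_quality_rate fraction of cells simulated as damaged.
#' @param low_quality_depth depth shrinkage factor for damaged cells.
#' @param low_quality_mito mitochondrial inflation factor for damaged cells.
#' @param cluster_types named map cluster id -> cell-type label (ground
#'   truth for annotation benchmarks); defaults to cluster ids.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class \code{sim_config}.
#' @seealso \code{\link{demo_sim_config}} for the shipped oncogene ON/OFF
#'   demonstration configuration.
#' @export
sim_config <- function(n_cells_per_condition,
                       cluster_proportions,
                       baseline_mean,
                       dispersion = 0.8,
                       marker_effects = NULL,
                       lr_effect = NULL,
                       mito_genes = NULL,
                       dropout_rate = 0.15,
                       low_quality_rate = 0,
                       low_quality_depth = 0.08,
                       low_quality_mito = 3,
                       cluster_types = NULL,
                       seed = 1L) {
  cfg <- list(n_cells_per_condition = n_cells_per_condition,
              cluster_proportions = cluster_proportions,
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              marker_effects = marker_effects,
              lr_effect = lr_effect,
              mito_genes = mito_genes,
              dropout_rate = dropout_rate,
              low_quality_rate = low_quality_rate,
              low_quality_depth = low_quality_depth,
              low_quality_mito = low_quality_mito,
              cluster_types = cluster_types,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  n <- cfg$n_cells_per_condition
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n))
    stop("n_cells_per_condition: must be a positive integer")
  cp <- cfg$cluster_proportions
  if (!is.list(cp) || is.null(names(cp)) || length(cp) < 1)
    stop("cluster_proportions: must be a named list (one vector per condition)")
  cl_names <- names(cp[[1]])
  for (cond in names(cp)) {
    p <- cp[[cond]]
    if (is.null(names(p)) || !identical(names(p), cl_names))
      stop("cluster_proportions: all conditions must use the same named clusters")
    if (any(!is.finite(p)) || any(p < 0))
      stop("cluster_proportions: probabilities must be finite and non-negative")
    if (abs(sum(p) - 1) > 1e-9)
      stop("cluster_proportions: vector for condition '", cond,
           "' sums to ", format(sum(p)), ", not 1")
  }
  bm <- cfg$baseline_mean
  if (is.null(names(bm)) || anyDuplicated(names(bm)))
    stop("baseline_mean: must be named with unique gene identifiers")
  if (any(!is.finite(bm)) || any(bm < 0))
    stop("baseline_mean: means must be finite and non-negative")
  disp <- cfg$dispersion
  if (any(!is.finite(disp)) || any(disp <= 0))
    stop("dispersion: must be positive and finite")
  if (!length(disp) %in% c(1L, length(bm)))
    stop("dispersion: must be a scalar or one value per gene")
  me <- cfg$marker_effects
  if (!is.null(me)) {
    if (!is.data.frame(me) || !all(c("cluster", "gene", "fc") %in% names(me)))
      stop("marker_effects: needs columns cluster, gene, fc")
    if (any(!is.finite(me$fc)) || any(me$fc < 0))
      stop("marker_effects: fold changes must be finite and non-negative")
    if (!all(me$gene %in% names(bm)))
      stop("marker_effects: unknown gene(s): ",
           paste(setdiff(me$gene, names(bm)), collapse = ", "))
    if (!all(me$cluster %in% cl_names))
      stop("marker_effects: unknown cluster(s): ",
           paste(setdiff(me$cluster, cl_names), collapse = ", "))
  }
  lr <- cfg$lr_effect
  if (!is.null(lr)) {
    need <- c("ligand", "receptor", "sender", "receiver", "fc")
    if (!all(need %in% names(lr)))
      stop("lr_effect: needs fields ", paste(need, collapse = ", "))
    if (!all(c(lr$ligand, lr$receptor) %in% names(bm)))
      stop("lr_effect: ligand/receptor not in gene universe")
    if (!all(c(lr$sender, lr$receiver) %in% cl_names))
      stop("lr_effect: sender/receiver not among clusters")
    if (is.null(names(lr$fc)) || !all(names(cp) %in% names(lr$fc)))
      stop("lr_effect: fc must be named by condition")
    if (any(!is.finite(lr$fc)) || any(lr$fc < 0))
      stop("lr_effect: fold changes must be finite and non-negative")
  }
  .check_prob(cfg$dropout_rate, "dropout_rate")
  .check_prob(cfg$low_quality_rate, "low_quality_rate")
  invisible(cfg)
}

#' Shipped oncogene ON/OFF demonstration configuration
#'
#' The default study conditions used throughout the package's examples and
#' tests: 15 clusters spanning the marker-defined cell types of an
#' autochthonous liver tumor (tumor cells, macrophages, neutrophils,
#' T cells, vascular cells, dendritic cells, fibroblasts, B cells), with
#' three planted condition effects mirroring what oncogene withdrawal does
#' to the tumor microenvironment:
#' \itemize{
#'   \item the T-cell cluster ("4") expands from 5\% of cells in the ON
#'     condition to 20\% in OFF, and its Cd8a/Cd69 positivity rises in OFF;
#'   \item an Il15 (tumor sender cluster "13") to Il2rb (T-cell receiver
#'     cluster "4") crosstalk signal is boosted in OFF;
#'   \item two clusters ("9", "11") are kept small so the n < 50 pooling
#'     rule is exercised.
#' }
#' Background gene baselines are gamma-distributed; 13 mitochondrial genes
#' carry elevated baselines so healthy cells sit near 3--4\% mitochondrial
#' fraction, and 6\% of cells are simulated as damaged so QC has work to do.
#'
#' @param n_cells_per_condition cells per condition (default 2000).
#' @param n_background_genes background (non-marker) genes (default 1259,
#'   for a 1300-gene universe).
#' @param seed integer seed.
#' @return A \code{\link{sim_config}} object.
#' @export
demo_sim_config <- function(n_cells_per_condition = 2000,
                            n_background_genes = 1259,
                            seed = 1L) {
  panel <- default_marker_panel()
  mito <- c("mt-Nd1", "mt-Nd2", "mt-Nd3", "mt-Nd4", "mt-Nd4l", "mt-Nd5",
            "mt-Nd6", "mt-Co1", "mt-Co2", "mt-Co3", "mt-Atp6", "mt-Atp8",
            "mt-Cytb")
  special <- c("Cd8a", "Cd69", "Ncr1", "Il15", "Il2rb", "Il15ra")
  marker_genes <- unique(unlist(panel, use.names = FALSE))
  background <- sprintf("Gene%04d", seq_len(n_background_genes))
  genes <- c(marker_genes, special, mito, background)

  # baselines: gamma background, modest marker baselines, housekeeping-like
  # mitochondria; drawn once, deterministically, from the config seed
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) + 1000L)
  bm <- c(stats::setNames(rep(0.5, length(marker_genes)), marker_genes),
          stats::setNames(c(0.4, 0.4, 0.4, 0.5, 0.5, 0.5), special),
          stats::setNames(rep(4, length(mito)), mito),
          stats::setNames(stats::rgamma(n_background_genes,
                                        shape = 0.6, scale = 2), background))

  cluster_types <- c(`0` = "tumor cells", `1` = "tumor cells",
                     `2` = "macrophages", `3` = "neutrophils",
                     `4` = "T cells", `5` = "tumor cells",
                     `6` = "macrophages", `7` = "CAFs",
                     `8` = "vascular cells", `9` = "dendritic cells",
                     `10` = "B cells", `11` = "B cells",
                     `12` = "vascular cells", `13` = "tumor cells",
                     `14` = "neutrophils")
  clusters <- names(cluster_types)
  immune <- c("macrophages", "neutrophils", "T cells", "dendritic cells",
              "B cells")

  props <- function(t_prop) {
    p <- stats::setNames(numeric(length(clusters)), clusters)
    p["4"] <- t_prop
    p[c("9", "11")] <- 0.01
    others <- setdiff(clusters, c("4", "9", "11"))
    w <- c(`0` = 1.6, `1` = 1.4, `2` = 1.2, `3` = 0.8, `5` = 1.2, `6` = 0.9,
           `7` = 1.0, `8` = 0.7, `10` = 0.9, `12` = 0.7, `13` = 1.0,
           `14` = 0.6)
    p[others] <- w[others] / sum(w[others]) * (1 - t_prop - 0.02)
    p
  }

  me <- do.call(rbind, lapply(clusters, function(cl) {
    type <- cluster_types[[cl]]
    rows <- data.frame(cluster = cl, gene = panel[[type]], fc = 30,
                       condition = NA_character_)
    if (type %in% immune)
      rows <- rbind(rows, data.frame(cluster = cl, gene = "Ptprc", fc = 4,
                                     condition = NA_character_))
    rows
  }))
  # condition-dependent T-subpopulation structure and a small NK admixture
  me <- rbind(me, data.frame(
    cluster = "4",
    gene = c("Cd8a", "Cd8a", "Cd69", "Cd69", "Ncr1", "Ncr1"),
    fc = c(4, 10, 1.5, 8, 1.5, 3),
    condition = c("ON", "OFF", "ON", "OFF", "ON", "OFF")))

  sim_config(
    n_cells_per_condition = n_cells_per_condition,
    cluster_proportions = list(ON = props(0.05), OFF = props(0.20)),
    baseline_mean = bm,
    dispersion = 0.8,
    marker_effects = me,
    lr_effect = list(ligand = "Il15", receptor = "Il2rb",
                     sender = "13", receiver = "4",
                     fc = c(ON = 2, OFF = 40)),
    mito_genes = mito,
    dropout_rate = 0.15,
    low_quality_rate = 0.06,
    cluster_types = cluster_types,
    seed = seed)
}

#' Simulate a two-condition gene-by-cell count matrix with ground truth
#'
#' Draws a seeded synthetic dataset under the model described in
#' \code{\link{sim_config}} and returns both the counts and the ground
#' truth (realized labels, planted marker genes per cluster, planted
#' ligand-receptor pair and enriched cell types) so downstream stages can
#' be benchmarked against what was actually planted.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with elements \code{matrix} (a \code{\link{count_matrix}})
#'   and \code{truth} (a \code{ground_truth} list: \code{cells},
#'   \code{cluster_types}, \code{markers}, \code{lr_pair},
#'   \code{enriched_types}, \code{genes}).
#' @examples
#' cfg <- demo_sim_config(n_cells_per_condition = 150, seed = 7)
#' sim <- simulate_counts(cfg)
#' sim$matrix
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  genes <- names(config$baseline_mean)
  n_genes <- length(genes)
  disp <- rep(config$dispersion, length.out = n_genes)
  size <- 1 / disp
  mito <- if (is.null(config$mito_genes))
    grep("^mt-", genes, ignore.case = TRUE, value = TRUE) else config$mito_genes
  is_mito <- genes %in% mito
  conditions <- names(config$cluster_proportions)
  clusters <- names(config$cluster_proportions[[1]])

  blocks <- list(); meta <- list(); idx <- 0L
  for (cond in conditions) {
    props <- config$cluster_proportions[[cond]]
    sizes <- as.vector(stats::rmultinom(1, config$n_cells_per_condition, props))
    names(sizes) <- clusters
    cell_no <- 0L
    for (cl in clusters) {
      ncell <- sizes[[cl]]
      if (ncell == 0L) next
      mu <- config$baseline_mean
      me <- config$marker_effects
      if (!is.null(me)) {
        hit <- me$cluster == cl &
          (if ("condition" %in% names(me))
             is.na(me$condition) | me$condition == cond else TRUE)
        for (j in which(hit)) mu[[me$gene[j]]] <- mu[[me$gene[j]]] * me$fc[j]
      }
      lr <- config$lr_effect
      if (!is.null(lr)) {
        if (cl == lr$sender) mu[[lr$ligand]] <- mu[[lr$ligand]] * lr$fc[[cond]]
        if (cl == lr$receiver) mu[[lr$receptor]] <- mu[[lr$receptor]] * lr$fc[[cond]]
      }
      lq <- stats::runif(ncell) < config$low_quality_rate
      mu_mat <- matrix(mu, nrow = n_genes, ncol = ncell)
      if (any(lq)) {
        adj <- ifelse(is_mito, config$low_quality_mito, config$low_quality_depth)
        mu_mat[, lq] <- mu_mat[, lq, drop = FALSE] * adj
      }
      counts <- matrix(stats::rnbinom(n_genes * ncell, mu = as.vector(mu_mat),
                                      size = rep(size, ncell)),
                       nrow = n_genes, ncol = ncell)
      if (config$dropout_rate > 0)
        counts <- counts *
          (stats::runif(n_genes * ncell) >= config$dropout_rate)
      idx <- idx + 1L
      cells <- sprintf("%s_%05d", cond, cell_no + seq_len(ncell))
      cell_no <- cell_no + ncell
      dimnames(counts) <- list(genes, cells)
      blocks[[idx]] <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                   "CsparseMatrix")
      meta[[idx]] <- data.frame(cell = cells, condition = cond, cluster = cl,
                                low_quality = lq)
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  m <- count_matrix(counts, meta[c("cell", "condition", "cluster")],
                    mito_genes = mito)
  m$cell_meta$low_quality <- meta$low_quality

  cluster_types <- config$cluster_types
  if (is.null(cluster_types))
    cluster_types <- stats::setNames(clusters, clusters)
  markers <- lapply(stats::setNames(clusters, clusters), function(cl) {
    me <- config$marker_effects
    g <- if (is.null(me)) character() else unique(me$gene[me$cluster == cl & me$fc > 1])
    sort(g)
  })
  p_on <- config$cluster_proportions[[1]]
  p_off <- config$cluster_proportions[[length(conditions)]]
  by_type <- function(p) tapply(p, cluster_types[names(p)], sum)
  enriched <- names(which(by_type(p_off) > by_type(p_on) + 1e-12))

  truth <- structure(list(
    cells = m$cell_meta[c("cell", "condition", "cluster")],
    cluster_types = cluster_types,
    markers = markers,
    lr_pair = config$lr_effect,
    enriched_types = enriched,
    genes = genes), class = "ground_truth")
  stopifnot(nrow(truth$cells) == ncol(m$counts))
  list(matrix = m, truth = truth)
}

#' Simulate a gene-set collection with one planted pathway
#'
#' Emulates a pathway database for enrichment benchmarking: the first set
#' ("planted_pathway") contains a stated fraction of the designated
#' cluster's planted marker genes, padded with random genes to the requested
#' size; all remaining sets are uniform random draws from the simulated gene
#' universe.
#'
#' @param truth a \code{ground_truth} from \code{\link{simulate_counts}}.
#' @param n_pathways number of gene sets (>= 0).
#' @param sizes set sizes, recycled over pathways; must not exceed the gene
#'   universe.
#' @param seed integer seed (byte-identical GMT output under a fixed seed).
#' @param designated_cluster cluster whose markers seed the planted pathway
#'   (default: the planted receiver cluster, else the first with markers).
#' @param overlap_fraction fraction of the designated markers included in
#'   the planted pathway (default 1).
#' @return Named list of gene vectors with attribute \code{source =
#'   "synthetic"}; the planted set is named \code{"planted_pathway"}.
#' @export
simulate_genesets <- function(truth, n_pathways = 50, sizes = 30, seed = 1L,
                              designated_cluster = NULL,
                              overlap_fraction = 1) {
  if (n_pathways < 0 || n_pathways != round(n_pathways))
    stop("n_pathways must be a non-negative integer")
  genes <- truth$genes
  if (any(sizes < 1) || any(sizes > length(genes)))
    stop("requested pathway size exceeds the gene universe (",
         length(genes), " genes)")
  .check_prob(overlap_fraction, "overlap_fraction")
  if (n_pathways == 0)
    return(structure(list(), source = "synthetic"))
  if (is.null(designated_cluster)) {
    designated_cluster <- if (!is.null(truth$lr_pair)) truth$lr_pair$receiver
      else names(which(lengths(truth$markers) > 0))[1]
  }
  markers <- truth$markers[[designated_cluster]]
  if (is.null(markers))
    stop("designated_cluster '", designated_cluster, "' has no planted markers")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sizes <- rep(sizes, length.out = n_pathways)

  n_keep <- ceiling(overlap_fraction * length(markers))
  kept <- if (n_keep > 0) sort(markers)[seq_len(n_keep)] else character()
  pad <- sample(setdiff(genes, kept), max(0, sizes[1] - length(kept)))
  sets <- list(planted_pathway = c(kept, pad))
  if (n_pathways > 1) {
    decoys <- lapply(seq_len(n_pathways - 1L),
                     function(i) sample(genes, sizes[i + 1L]))
    names(decoys) <- sprintf("decoy_pathway_%03d", seq_len(n_pathways - 1L))
    sets <- c(sets, decoys)
  }
  structure(sets, source = "synthetic")
}

#' Simulate a ligand-receptor pair table with decoys
#'
#' Returns the planted pair (and, if present in the universe, the shared
#' alpha-chain pairing of the same ligand) followed by decoy pairs drawn
#' uniformly from the background gene universe, for specificity
#' benchmarking of the interaction score.
#'
#' @param truth a \code{ground_truth} from \code{\link{simulate_counts}}.
#' @param n_decoys number of decoy pairs (default 60).
#' @param seed integer seed.
#' @return data.frame with columns \code{ligand}, \code{receptor},
#'   \code{pair}.
#' @export
simulate_lr_pairs <- function(truth, n_decoys = 60, seed = 1L) {
  if (is.null(truth$lr_pair))
    stop("ground truth has no planted ligand-receptor pair")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  planted <- data.frame(ligand = truth$lr_pair$ligand,
                        receptor = truth$lr_pair$receptor)
  if ("Il15ra" %in% truth$genes && planted$ligand == "Il15")
    planted <- rbind(planted, data.frame(ligand = "Il15", receptor = "Il15ra"))
  pool <- setdiff(truth$genes,
                  c(planted$ligand, planted$receptor,
                    unlist(truth$markers, use.names = FALSE)))
  decoys <- data.frame(ligand = sample(pool, n_decoys),
                       receptor = sample(pool, n_decoys))
  pairs <- rbind(planted, decoys)
  pairs$pair <- paste(pairs$ligand, pairs$receptor, sep = "-")
  pairs
}

#' Simulate a tumor-burden time series
#'
#' Log burden follows piecewise-linear growth at \code{growth_rate} per day
#' until \code{switch_day}, then decays at \code{regression_rate} per day,
#' with Gaussian noise on the log scale; values are strictly positive.
#' With \code{type = "caliper"} the burden is converted to length/width
#' pairs under the ellipsoid convention (length = 1.2 x width) so that
#' \code{\link{tumor_volume}} recovers it.
#'
#' @param model list with \code{growth_rate}, \code{regression_rate},
#'   \code{switch_day}, \code{noise_sd}, \code{seed}.
#' @param days strictly increasing numeric vector of measurement days.
#' @param n_subjects subjects to draw (default 3).
#' @param baseline burden at day 0 (default 100, arbitrary units).
#' @param type \code{"radiance"} (one burden column) or \code{"caliper"}
#'   (length_mm / width_mm columns).
#' @return data.frame with columns \code{subject}, \code{group},
#'   \code{day}, and \code{radiance} or \code{length_mm} + \code{width_mm}.
#' @export
simulate_tumor_series <- function(model, days, n_subjects = 3,
                                  baseline = 100, type = c("radiance", "caliper")) {
  type <- match.arg(type)
  if (length(days) < 1 || any(diff(days) <= 0))
    stop("`days` must be strictly increasing")
  for (f in c("growth_rate", "regression_rate", "switch_day", "noise_sd"))
    if (is.null(model[[f]]) || !is.finite(model[[f]]))
      stop("model field `", f, "` must be a finite number")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(model$seed %||% 1L))
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    lb <- log(baseline) + model$growth_rate * pmin(days, model$switch_day) -
      model$regression_rate * pmax(0, days - model$switch_day) +
      stats::rnorm(length(days), sd = model$noise_sd)
    data.frame(subject = sprintf("m%02d", s), group = "sim",
               day = days, burden = exp(lb))
  }))
  if (type == "caliper") {
    w <- (6 * out$burden / (1.2 * pi))^(1 / 3)
    out$length_mm <- 1.2 * w
    out$width_mm <- w
    out$burden <- NULL
  } else {
    names(out)[names(out) == "burden"] <- "radiance"
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
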