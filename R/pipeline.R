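#' Pipeline configuration
#'
#' Collects every stage threshold of the end-to-end analysis in one place.
#' The defaults are the constants the analysis is defined with: QC at 200
#' detected genes and 10\% mitochondrial content, ligand-receptor
#' detection at 0.1 CPM and prioritization above a score of 20,
#' small-cluster pooling below 50 cells, a background universe of 20,000
#' genes, and alpha 0.05. Every value is echoed into the run log so any
#' override is visible.
#'
#' @param out_dir directory for the report bundle.
#' @param seed integer seed driving every stochastic stage.
#' @param counts_path input counts (MTX directory or dense table) or
#'   \code{NULL} to simulate from \code{sim}.
#' @param meta_path cell metadata TSV (dense input only).
#' @param sim a \code{\link{sim_config}} used when \code{counts_path} is
#'   \code{NULL}; default \code{demo_sim_config(seed = seed)}.
#' @param pairs_path ligand-receptor pair TSV; \code{NULL} uses planted +
#'   decoy pairs for simulated input, else \code{\link{default_lr_pairs}}.
#' @param gmt_path gene-set GMT; \code{NULL} uses simulated sets (with the
#'   planted pathway) for simulated input.
#' @param conditions the two condition labels, table column order.
#' @param contrast length-2: condition contrast for score deltas
#'   (\code{contrast[1] - contrast[2]}).
#' @param min_genes,max_mito QC thresholds.
#' @param detect_cpm,min_score ligand-receptor thresholds.
#' @param min_n_pool pooling threshold for small clusters.
#' @param background enrichment universe size (integer) or
#'   \code{"observed"}.
#' @param alpha significance level for reporting.
#' @param adjust multiple-testing method (default \code{"BH"}).
#' @param min_log2fc marker-gene fold-change threshold.
#' @param subpop_parent_type,subpop_genes,subpop_threshold T-subpopulation
#'   definition: parent cell type, predicate genes, positivity threshold on
#'   the raw count.
#' @param n_decoy_pairs,n_pathways,pathway_size sizes of the simulated
#'   pair table and gene-set collection (simulated input only).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            counts_path = NULL,
                            meta_path = NULL,
                            sim = NULL,
                            pairs_path = NULL,
                            gmt_path = NULL,
                            conditions = c("ON", "OFF"),
                            contrast = c("OFF", "ON"),
                            min_genes = 200,
                            max_mito = 0.10,
                            detect_cpm = 0.1,
                            min_score = 20,
                            min_n_pool = 50,
                            background = 20000,
                            alpha = 0.05,
                            adjust = "BH",
                            min_log2fc = 0.25,
                            subpop_parent_type = "T cells",
                            subpop_genes = c("Cd8a", "Cd69"),
                            subpop_threshold = 1,
                            n_decoy_pairs = 60,
                            n_pathways = 50,
                            pathway_size = 30) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (is.null(cfg$sim) && is.null(cfg$counts_path))
    cfg$sim <- demo_sim_config(seed = cfg$seed)
  if (length(conditions) != 2 || length(contrast) != 2 ||
      !setequal(contrast, conditions))
    stop("`conditions` and `contrast` must be the same two labels")
  structure(cfg, class = "pipeline_config")
}

#' Demonstration pipeline configuration (simulated oncogene ON/OFF data)
#'
#' The shipped study conditions: 2,000 cells per condition from
#' \code{\link{demo_sim_config}}, 60 decoy ligand-receptor pairs, 50
#' pathways with one planted set, and the enrichment background set to the
#' observed simulated universe — the calibrated choice when the gene
#' universe is a 1,300-gene subsample rather than a full transcriptome
#' (see the package vignette).
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_cells_per_condition cells per condition (default 2000).
#' @return A \code{\link{pipeline_config}}.
#' @export
demo_pipeline_config <- function(out_dir, seed = 1L,
                                 n_cells_per_condition = 2000) {
  pipeline_config(out_dir = out_dir, seed = seed,
                  sim = demo_sim_config(
                    n_cells_per_condition = n_cells_per_condition,
                    seed = seed),
                  background = "observed")
}

#' Run the full two-condition analysis pipeline
#'
#' Chains simulate (or read) -> QC -> CPM -> cluster means -> marker-panel
#' annotation -> composition and T-subpopulation Fisher tests ->
#' ligand-receptor scoring, prioritization and condition deltas ->
#' marker finding, small-cluster pooling and pathway enrichment, writing
#' every intermediate table, a run log and a checksum manifest to
#' \code{config$out_dir}. The run is deterministic: identical config and
#' seed produce byte-identical outputs (and therefore manifests). Any
#' stage failure aborts with the stage name; tables written before the
#' failure are preserved.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{oncoswitch_run} with all stage results and
#'   the written file paths.
#' @examples
#' \donttest{
#' run <- run_pipeline(demo_pipeline_config(tempfile("demo"), seed = 1,
#'                                          n_cells_per_condition = 300))
#' print(run)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv(df, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- input -----------------------------------------------------------
  truth <- NULL
  input <- stage("input", {
    if (is.null(config$counts_path)) {
      sim <- simulate_counts(config$sim)
      truth <- sim$truth
      sim$matrix
    } else {
      read_counts(config$counts_path, config$meta_path)
    }
  })

  # --- qc + normalization ---------------------------------------------
  qc <- stage("qc", qc_filter(input, config$min_genes, config$max_mito))
  qc_rep <- attr(qc, "qc")
  emit(data.frame(metric = names(qc_rep),
                  value = unlist(qc_rep, use.names = FALSE)), "qc_report.tsv")
  cpmx <- stage("cpm", cpm_normalize(qc))

  # --- annotation ------------------------------------------------------
  profile <- stage("annotate", {
    p <- cluster_means(cpmx)
    annotate_clusters(p, margin = 1.2)
  })
  emit(data.frame(cluster = names(profile$n_cells),
                  n_cells = unname(profile$n_cells),
                  cell_type = unname(profile$cell_type[names(profile$n_cells)])),
       "annotation.tsv")
  cell_type <- profile$cell_type[qc$cell_meta$cluster]

  # --- composition -----------------------------------------------------
  meta <- qc$cell_meta
  meta$cell_type <- unname(cell_type)
  comp <- stage("composition", {
    tab <- build_composition(meta, conditions = config$conditions)
    fet_enrichment(tab, adjust = config$adjust)
  })
  emit(comp, "composition_fet.tsv")

  subpop <- stage("subpopulations", {
    parent <- meta$cell_type == config$subpop_parent_type
    if (!any(parent)) {
      warning("no cells annotated as '", config$subpop_parent_type,
              "'; subpopulation stage skipped")
      NULL
    } else {
      tab <- subpop_counts(qc, parent, config$subpop_genes,
                           threshold = config$subpop_threshold,
                           conditions = config$conditions)
      fet_enrichment(tab, adjust = config$adjust)
    }
  })
  if (!is.null(subpop)) emit(subpop, "subpop_fet.tsv")

  # --- ligand-receptor scoring ----------------------------------------
  lr <- stage("lr_scoring", {
    pairs <- if (!is.null(config$pairs_path)) read_lr_pairs(config$pairs_path)
      else if (!is.null(truth) && !is.null(truth$lr_pair))
        simulate_lr_pairs(truth, n_decoys = config$n_decoy_pairs,
                          seed = config$seed + 2L)
      else default_lr_pairs()
    profiles <- lapply(stats::setNames(config$conditions, config$conditions),
                       function(cond) {
      idx <- cpmx$cell_meta$condition == cond
      sub <- structure(list(cpm = cpmx$cpm[, idx, drop = FALSE],
                            cell_meta = cpmx$cell_meta[idx, , drop = FALSE]),
                       class = "cpm_matrix")
      cluster_means(sub)
    })
    scored <- score_pairs(profiles, pairs, detect_cpm = config$detect_cpm)
    kept <- prioritize_pairs(scored, min_score = config$min_score)
    kk <- paste(kept$pair, kept$sender, kept$receiver)
    scored$prioritized <- paste(scored$pair, scored$sender, scored$receiver) %in% kk
    delta <- condition_delta(scored, conditions = config$contrast)
    list(pairs = pairs, scores = scored, prioritized = kept, delta = delta)
  })
  emit(lr$scores, "lr_scores.tsv")
  emit(lr$delta, "lr_delta.tsv")

  # --- markers + pathway enrichment -----------------------------------
  enr <- stage("enrichment", {
    mk <- find_markers(cpmx, min_log2fc = config$min_log2fc,
                       alpha = config$alpha)
    sets <- split(mk$gene, mk$cluster)
    sizes <- table(qc$cell_meta$cluster)
    sizes <- stats::setNames(as.integer(sizes), names(sizes))
    sets <- sets[names(sets) %in% names(sizes)]
    pooled <- pool_small_clusters(sets, sizes, min_n = config$min_n_pool)
    collection <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
      else if (!is.null(truth))
        simulate_genesets(truth, n_pathways = config$n_pathways,
                          sizes = config$pathway_size,
                          seed = config$seed + 3L)
      else stop("no gene-set collection: supply `gmt_path`")
    res <- enrich_pathways(pooled$marker_sets, collection,
                           universe = rownames(qc$counts),
                           background = config$background,
                           adjust = config$adjust)
    list(markers = mk, pooled = pooled, collection = collection,
         results = res)
  })
  emit(enr$markers, "markers.tsv")
  emit(enr$results, "enrichment.tsv")

  # --- log + manifest --------------------------------------------------
  log_fields <- c("seed", "conditions", "contrast", "min_genes", "max_mito",
                  "detect_cpm", "min_score", "min_n_pool", "background",
                  "alpha", "adjust", "min_log2fc", "subpop_parent_type",
                  "subpop_genes", "subpop_threshold", "n_decoy_pairs",
                  "n_pathways", "pathway_size")
  log_lines <- c(
    paste0("oncoswitch ", as.character(utils::packageVersion("oncoswitch"))),
    vapply(log_fields, function(f)
      paste0(f, " = ", paste(config[[f]], collapse = ",")), ""))
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  written <- c(written, log_path)

  rel <- basename(written)
  manifest <- data.frame(file = rel,
                         md5 = unname(tools::md5sum(written)))
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))

  structure(list(config = config, input = input, truth = truth, qc = qc,
                 profile = profile, composition = comp, subpop = subpop,
                 lr = lr, enrichment = enr, manifest = manifest,
                 files = c(written, file.path(config$out_dir, "manifest.tsv"))),
            class = "oncoswitch_run")
}

#' @export
print.oncoswitch_run <- function(x, ...) {
  qc <- attr(x$qc, "qc")
  cat("oncoswitch pipeline run\n")
  cat(sprintf("  cells: %d in, %d retained by QC\n", qc$n_input, qc$n_retained))
  cat(sprintf("  clusters: %d; cell types: %s\n",
              length(x$profile$n_cells),
              paste(sort(unique(x$profile$cell_type)), collapse = ", ")))
  top_comp <- utils::head(x$composition, 3)
  cat("  top composition shifts (FET):\n")
  for (i in seq_len(nrow(top_comp)))
    cat(sprintf("    %-16s q = %.3g\n", top_comp$group[i], top_comp$q_value[i]))
  top_delta <- utils::head(x$lr$delta, 1)
  if (nrow(top_delta))
    cat(sprintf("  top L-R condition delta: %s (%s -> %s), delta = %.3g\n",
                top_delta$pair, top_delta$sender, top_delta$receiver,
                top_delta$delta))
  er <- x$enrichment$results
  top_enr <- utils::head(er[order(er$q_value, er$p_value), , drop = FALSE], 1)
  if (nrow(top_enr))
    cat(sprintf("  top pathway: %s in group %s (q = %.3g)\n",
                top_enr$pathway, top_enr$group, top_enr$q_value))
  cat("  outputs:", dirname(x$files[1]), "\n")
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the arguments of \code{\link{pipeline_config}}; the
#' \code{sim} field, if present, is passed to \code{\link{sim_config}}
#' after converting \code{cluster_proportions}, \code{baseline_mean} and
#' \code{marker_effects} from their YAML forms.
#'
#' @param path YAML file.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.list(y))
    stop("config file '", path, "' does not contain a YAML mapping")
  if (!is.null(y$sim)) {
    s <- y$sim
    s$cluster_proportions <- lapply(s$cluster_proportions, unlist)
    s$baseline_mean <- unlist(s$baseline_mean)
    if (!is.null(s$marker_effects))
      s$marker_effects <- do.call(rbind.data.frame, s$marker_effects)
    if (!is.null(s$lr_effect)) s$lr_effect$fc <- unlist(s$lr_effect$fc)
    if (!is.null(s$cluster_types)) s$cluster_types <- unlist(s$cluster_types)
    y$sim <- do.call(sim_config, s)
  }
  do.call(pipeline_config, y)
}
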