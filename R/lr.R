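#' Curated mouse ligand-receptor pair table
#'
#' A small default table of well-established mouse ligand-receptor
#' couplings for tumor-immune crosstalk screens, including the IL-15 axis
#' (Il15-Il2rb signalling chain and Il15-Il15ra alpha chain). Users with a
#' dedicated interaction database should supply their own table; any
#' data.frame with \code{ligand} and \code{receptor} columns works.
#'
#' @return data.frame with columns \code{ligand}, \code{receptor},
#'   \code{pair}.
#' @export
default_lr_pairs <- function() {
  p <- rbind(
    c("Il15", "Il2rb"), c("Il15", "Il15ra"),
    c("Il2", "Il2ra"), c("Il2", "Il2rb"),
    c("Il6", "Il6ra"), c("Il10", "Il10ra"),
    c("Ifng", "Ifngr1"), c("Tnf", "Tnfrsf1a"),
    c("Tgfb1", "Tgfbr1"), c("Csf1", "Csf1r"),
    c("Ccl2", "Ccr2"), c("Ccl17", "Ccr4"), c("Ccl5", "Ccr5"),
    c("Cxcl9", "Cxcr3"), c("Cxcl10", "Cxcr3"), c("Cxcl12", "Cxcr4"),
    c("Cd274", "Pdcd1"), c("Kitl", "Kit"),
    c("Vegfa", "Flt1"), c("Pdgfa", "Pdgfra"))
  out <- data.frame(ligand = p[, 1], receptor = p[, 2])
  out$pair <- paste(out$ligand, out$receptor, sep = "-")
  out
}

#' Ligand-receptor interaction scores between cluster pairs
#'
#' For each condition and every ordered (sender, receiver) cluster pair —
#' self-pairs included, covering autocrine signalling — the interaction
#' score of a ligand-receptor pair is the product of the ligand's mean CPM
#' in the sender cluster and the receptor's mean CPM in the receiver
#' cluster. A pair is \emph{detected} only when both cluster means exceed
#' \code{detect_cpm} (strictly; default 0.1 CPM, a dropout guard);
#' undetected records keep a score of 0 rather than being dropped, so the
#' output stays auditable. \code{viz_score} is the score scaled by 10, a
#' convention used for visualization only — thresholds always apply to the
#' unscaled score.
#'
#' @param profiles named list of \code{cluster_profile} objects, one per
#'   condition, sharing a gene universe.
#' @param pairs data.frame with \code{ligand} and \code{receptor} columns
#'   (default \code{\link{default_lr_pairs}}); pairs whose genes are
#'   missing from the profiles are skipped with a warning.
#' @param detect_cpm detection threshold on both cluster means
#'   (default 0.1).
#' @return data.frame of class \code{lr_scores}: one row per (pair,
#'   sender, receiver, condition) with \code{mean_cpm_ligand},
#'   \code{mean_cpm_receptor}, \code{detected}, \code{score},
#'   \code{viz_score}.
#' @export
score_pairs <- function(profiles, pairs = default_lr_pairs(),
                        detect_cpm = 0.1) {
  if (!is.list(profiles) || is.null(names(profiles)) ||
      !all(vapply(profiles, inherits, TRUE, "cluster_profile")))
    stop("`profiles` must be a named list of cluster_profile objects")
  if (!is.data.frame(pairs) || nrow(pairs) == 0)
    stop("`pairs` must be a non-empty data.frame with ligand and receptor")
  genes <- rownames(profiles[[1]]$means)
  for (p in profiles) {
    if (!identical(rownames(p$means), genes))
      stop("condition profiles must share one gene universe")
    if (ncol(p$means) == 0)
      stop("a condition profile has no clusters (no cells left?)")
  }
  ok <- pairs$ligand %in% genes & pairs$receptor %in% genes
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) skipped: gene(s) absent from the profiles")
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no scoreable pairs left")
  if (is.null(pairs$pair))
    pairs$pair <- paste(pairs$ligand, pairs$receptor, sep = "-")

  res <- lapply(names(profiles), function(cond) {
    means <- profiles[[cond]]$means
    cl <- colnames(means)
    grid <- expand.grid(sender = cl, receiver = cl, pair_idx = seq_len(nrow(pairs)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lig <- pairs$ligand[grid$pair_idx]
    rec <- pairs$receptor[grid$pair_idx]
    ml <- means[cbind(lig, grid$sender)]
    mr <- means[cbind(rec, grid$receiver)]
    detected <- ml > detect_cpm & mr > detect_cpm
    score <- ifelse(detected, ml * mr, 0)
    data.frame(pair = pairs$pair[grid$pair_idx], ligand = lig, receptor = rec,
               sender = grid$sender, receiver = grid$receiver,
               condition = cond, mean_cpm_ligand = ml, mean_cpm_receptor = mr,
               detected = detected, score = score, viz_score = 10 * score,
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  class(out) <- c("lr_scores", class(out))
  out
}

#' Prioritize interaction triples by score
#'
#' Keeps a (pair, sender, receiver) triple when its unscaled score is
#' strictly greater than \code{min_score} in at least one condition; both
#' conditions' records of a kept triple are retained so condition contrasts
#' remain computable. A triple scoring exactly \code{min_score} everywhere
#' is dropped (strict inequality). The threshold applies before any
#' visualization scaling.
#'
#' @param records an \code{lr_scores} data.frame from
#'   \code{\link{score_pairs}}.
#' @param min_score prioritization threshold (default 20).
#' @return The filtered records.
#' @export
prioritize_pairs <- function(records, min_score = 20) {
  stopifnot(is.data.frame(records),
            all(c("pair", "sender", "receiver", "condition", "score")
                %in% names(records)))
  key <- paste(records$pair, records$sender, records$receiver, sep = "\r")
  best <- tapply(records$score, key, max)
  keep <- key %in% names(best)[best > min_score]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Condition contrast of interaction scores
#'
#' For every (pair, sender, receiver) triple present in both conditions,
#' computes the score difference and the pseudocounted score ratio between
#' the two conditions. Triples observed in one condition only are reported
#' with missing contrasts rather than silently dropped.
#'
#' @param records an \code{lr_scores} data.frame.
#' @param conditions length-2 character: the contrast is
#'   \code{conditions[1] - conditions[2]} (e.g. \code{c("OFF", "ON")} for
#'   the gain after oncogene withdrawal).
#' @param eps pseudocount for the ratio (default 1).
#' @return data.frame with one row per triple: scores per condition,
#'   \code{delta} and \code{ratio}, sorted by decreasing delta.
#' @export
condition_delta <- function(records, conditions = c("OFF", "ON"), eps = 1) {
  stopifnot(is.data.frame(records), length(conditions) == 2)
  if (!all(conditions %in% records$condition))
    stop("records do not contain both conditions: ",
         paste(conditions, collapse = ", "))
  r1 <- records[records$condition == conditions[1], , drop = FALSE]
  r2 <- records[records$condition == conditions[2], , drop = FALSE]
  key <- function(d) paste(d$pair, d$sender, d$receiver, sep = "\r")
  k1 <- key(r1); k2 <- key(r2)
  all_k <- union(k1, k2)
  i1 <- match(all_k, k1); i2 <- match(all_k, k2)
  base <- ifelse(is.na(i1), i2, i1)
  pick <- function(col) ifelse(is.na(i1), r2[[col]][i2], r1[[col]][i1])
  s1 <- r1$score[i1]; s2 <- r2$score[i2]
  out <- data.frame(pair = pick("pair"), ligand = pick("ligand"),
                    receptor = pick("receptor"), sender = pick("sender"),
                    receiver = pick("receiver"),
                    score_1 = s1, score_2 = s2,
                    delta = s1 - s2, ratio = (s1 + eps) / (s2 + eps),
                    row.names = NULL)
  names(out)[match(c("score_1", "score_2"), names(out))] <-
    paste0("score_", conditions)
  out[order(-out$delta, out$pair, out$sender, out$receiver), , drop = FALSE]
}
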