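# Expression filtering, fold-change ranking, cross-species concordance and
# profile clustering of differentially expressed orthologs.

#' Filter genes by minimum expression
#'
#' Keeps a gene iff there exists a time point at which at least
#' `min_replicates` replicate values reach `rpkm_threshold`; equivalently,
#' genes whose expression fails this at every time point are filtered out.
#' The same rule serves coding genes (threshold 3 RPKM) and lncRNAs
#' (threshold 0.5 RPKM).
#'
#' @param tc a `TimeCourseMatrix`.
#' @param rpkm_threshold expression threshold (> 0), compared with `>=`.
#' @param min_replicates replicates required at a single time point.
#' @return character vector of kept gene ids.
#' @export
filter_expressed <- function(tc, rpkm_threshold, min_replicates = 2) {
  stopifnot(inherits(tc, "TimeCourseMatrix"))
  if (rpkm_threshold <= 0) stop("`rpkm_threshold` must be positive")
  if (min_replicates > tc$n_replicates)
    stop(sprintf("`min_replicates` (%d) exceeds available replicates (%d)",
                 min_replicates, tc$n_replicates))
  keep <- vapply(seq_len(nrow(tc$values)), function(i) {
    passes <- tapply(tc$values[i, ] >= rpkm_threshold, tc$col_time, sum)
    any(passes >= min_replicates)
  }, TRUE)
  rownames(tc$values)[keep]
}

#' Call differentially expressed (gene, time point) records
#'
#' Strict cutoffs: `fdr < fdr_cut` and `|log2_fc| > fc_cut`.
#'
#' @param de_table data.frame with `gene_id`, `timepoint`, `log2_fc`, `fdr`.
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param fc_cut absolute log2 fold-change cutoff (default 1).
#' @return the passing records with an added `direction` column ("up"/"down").
#' @export
call_de <- function(de_table, fdr_cut = 0.05, fc_cut = 1.0) {
  keep <- de_table$fdr < fdr_cut & abs(de_table$log2_fc) > fc_cut
  out <- de_table[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2_fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Top-fraction fold-change ranking at one time point
#'
#' Among records at `timepoint` with `fdr < fdr_cut` and `|log2_fc| >=
#' fc_floor`, splits by sign, sorts each direction by `|log2_fc|` descending
#' (ties broken by gene id ascending) and keeps the top
#' `ceiling(fraction * n)` of each.
#'
#' @param de_table DE table data.frame.
#' @param timepoint the time point (hours) to rank.
#' @param fdr_cut FDR cutoff.
#' @param fc_floor minimum absolute log2 fold change for candidacy.
#' @param fraction fraction of each direction kept, in (0, 1].
#' @return list with ordered character vectors `up` and `down`.
#' @export
rank_top20 <- function(de_table, timepoint, fdr_cut = 0.05, fc_floor = 0.3,
                       fraction = 0.2) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  cand <- de_table[de_table$timepoint == timepoint &
                   de_table$fdr < fdr_cut &
                   abs(de_table$log2_fc) >= fc_floor, , drop = FALSE]
  take <- function(d) {
    sub <- cand[if (d == "up") cand$log2_fc > 0 else cand$log2_fc < 0, , drop = FALSE]
    if (nrow(sub) == 0L) return(character())
    ord <- order(-abs(sub$log2_fc), sub$gene_id)
    sub$gene_id[ord][seq_len(ceiling(fraction * nrow(sub)))]
  }
  list(up = take("up"), down = take("down"))
}

#' Ranked gene sets across all time points
#'
#' Applies [rank_top20()] at every time point present in the table and merges
#' the per-time-point lists into one gene set per direction ("all the time
#' points merged").
#'
#' @inheritParams rank_top20
#' @return an object of class `RankedSets`: list with `by_timepoint` (named
#'   list of `rank_top20` results) and `merged` (list `up`, `down` of unique
#'   gene ids).
#' @export
ranked_sets <- function(de_table, fdr_cut = 0.05, fc_floor = 0.3,
                        fraction = 0.2) {
  tps <- sort(unique(de_table$timepoint))
  by_tp <- lapply(tps, function(tp)
    rank_top20(de_table, tp, fdr_cut, fc_floor, fraction))
  names(by_tp) <- as.character(tps)
  merged <- list(
    up = unique(unlist(lapply(by_tp, `[[`, "up"), use.names = FALSE)),
    down = unique(unlist(lapply(by_tp, `[[`, "down"), use.names = FALSE)))
  structure(list(by_timepoint = by_tp, merged = merged), class = "RankedSets")
}

#' Cross-species concordant ortholog pairs
#'
#' A pair (h, m) is concordant in direction d iff h is in the human merged-d
#' set and m in the mouse merged-d set (hits may come from different time
#' points); a pair can appear for both directions.
#'
#' @param ranked_h,ranked_m `RankedSets` for the two species.
#' @param ortho one-to-one ortholog map (`human_gene`, `mouse_gene`).
#' @return data.frame with `human_gene`, `mouse_gene`, `direction`.
#' @export
concordant_pairs <- function(ranked_h, ranked_m, ortho) {
  out <- do.call(rbind, lapply(c("up", "down"), function(d) {
    hit <- ortho$human_gene %in% ranked_h$merged[[d]] &
      ortho$mouse_gene %in% ranked_m$merged[[d]]
    if (!any(hit)) return(NULL)
    data.frame(human_gene = ortho$human_gene[hit],
               mouse_gene = ortho$mouse_gene[hit],
               direction = d, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(human_gene = character(), mouse_gene = character(),
                      direction = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-gene expression profiles (replicate means of log2(RPKM + 1))
#'
#' @param tc a `TimeCourseMatrix`.
#' @param genes gene ids to extract (default all).
#' @param standardize z-score each profile across time points; constant
#'   profiles are dropped (reported via the `dropped` attribute).
#' @return genes x timepoints numeric matrix.
#' @export
profile_matrix <- function(tc, genes = NULL, standardize = FALSE) {
  stopifnot(inherits(tc, "TimeCourseMatrix"))
  genes <- genes %||% rownames(tc$values)
  missing <- setdiff(genes, rownames(tc$values))
  if (length(missing))
    stop(sprintf("genes absent from matrix: %s", paste(missing, collapse = ", ")))
  lg <- log2(tc$values[genes, , drop = FALSE] + 1)
  prof <- t(apply(lg, 1L, function(r) tapply(r, tc$col_time, mean)))
  colnames(prof) <- as.character(sort(unique(tc$col_time)))
  dropped <- character()
  if (standardize) {
    sds <- apply(prof, 1L, sd)
    dropped <- rownames(prof)[sds == 0]
    prof <- prof[sds > 0, , drop = FALSE]
    prof <- t(scale(t(prof)))
  }
  attr(prof, "dropped") <- dropped
  prof
}

#' Joint k-means clustering of both species' DE profiles
#'
#' Builds per-gene profiles (replicate-averaged log2(RPKM + 1), z-scored
#' across time points), pools the two species' selected genes and runs
#' k-means (Euclidean, `restarts` random initializations, best fit kept).
#' Ortholog pairs whose members land in the same cluster are reported as
#' sharing their expression profile.
#'
#' @param tc_h,tc_m `TimeCourseMatrix` for the two species (same time grid).
#' @param genes_h,genes_m DE gene ids clustered per species.
#' @param ortho one-to-one ortholog map.
#' @param k number of clusters (default 30; must not exceed the pooled count).
#' @param restarts k-means restarts (`nstart`).
#' @param seed integer seed.
#' @return list with `assignments` (named integer vector), `pairs`
#'   (data.frame `human_gene`, `mouse_gene`, `cluster`), and `tot_withinss`.
#' @export
cluster_profiles_kmeans <- function(tc_h, tc_m, genes_h, genes_m, ortho,
                                    k = 30, restarts = 10, seed = 1) {
  if (!isTRUE(all.equal(tc_h$timepoints, tc_m$timepoints)))
    stop("the two species must share the time grid")
  ph <- profile_matrix(tc_h, genes_h, standardize = TRUE)
  pm <- profile_matrix(tc_m, genes_m, standardize = TRUE)
  pooled <- rbind(ph, pm)
  if (nrow(pooled) < k)
    stop(sprintf("fewer pooled genes (%d) than clusters (k = %d)", nrow(pooled), k))
  km <- withr::with_seed(as.integer(seed),
                         kmeans(pooled, centers = k, nstart = restarts,
                                iter.max = 100))
  assign <- setNames(km$cluster, rownames(pooled))
  both <- ortho$human_gene %in% rownames(ph) & ortho$mouse_gene %in% rownames(pm)
  o <- ortho[both, , drop = FALSE]
  same <- assign[o$human_gene] == assign[o$mouse_gene]
  pairs <- data.frame(human_gene = o$human_gene[same],
                      mouse_gene = o$mouse_gene[same],
                      cluster = unname(assign[o$human_gene[same]]),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(assignments = assign, pairs = pairs, tot_withinss = km$tot.withinss)
}

#' Hierarchical leaf order for heatmap export
#'
#' Ward minimum-variance clustering on Euclidean distances
#' (`hclust(dist(x), "ward.D2")`); rows containing NaN/NA are rejected.
#'
#' @param mat numeric profile matrix with rownames.
#' @return character vector: rownames in dendrogram leaf order.
#' @export
hierarchical_order <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  if (any(!is.finite(mat))) stop("non-finite values in profile matrix")
  hc <- hclust(dist(mat), method = "ward.D2")
  rownames(mat)[hc$order]
}

#' Pearson correlation of ortholog expression profiles
#'
#' Correlates the two species' replicate-averaged log2(RPKM + 1) profiles over
#' the shared time points.  Pairs in which either profile is constant get
#' `r = NA` and `constant = TRUE`.
#'
#' @param tc_h,tc_m `TimeCourseMatrix` for the two species (same time grid).
#' @param pairs data.frame with `human_gene`, `mouse_gene`.
#' @return data.frame `human_gene`, `mouse_gene`, `r`, `constant`.
#' @export
correlate_ortholog_expression <- function(tc_h, tc_m, pairs) {
  if (!isTRUE(all.equal(tc_h$timepoints, tc_m$timepoints)))
    stop("the two species must share the time grid")
  ph <- profile_matrix(tc_h, intersect(pairs$human_gene, rownames(tc_h$values)))
  pm <- profile_matrix(tc_m, intersect(pairs$mouse_gene, rownames(tc_m$values)))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    hg <- pairs$human_gene[i]; mg <- pairs$mouse_gene[i]
    if (!hg %in% rownames(ph) || !mg %in% rownames(pm)) return(NULL)
    a <- ph[hg, ]; b <- pm[mg, ]
    const <- sd(a) == 0 || sd(b) == 0
    data.frame(human_gene = hg, mouse_gene = mg,
               r = if (const) NA_real_ else cor(a, b),
               constant = const, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(human_gene = character(), mouse_gene = character(),
                      r = numeric(), constant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
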