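# lncRNA-specific filtering, biotype representation testing, nearest coding
# gene assignment and lncRNA-mRNA co-expression.

#' Expressed lncRNA sets before and after activation
#'
#' Applies the [filter_expressed()] keep-rule (>= `min_replicates` replicates
#' reaching `threshold` RPKM at some time point) separately to the
#' pre-activation (0 h) samples and the post-activation time points.
#'
#' @param matrix_preactivation `TimeCourseMatrix` of the 0 h samples.
#' @param matrix_postactivation `TimeCourseMatrix` of the later time points.
#' @param threshold RPKM threshold (default 0.5 for lncRNAs).
#' @param min_replicates replicates required (default 2).
#' @return list with character vectors `expressed_before`, `expressed_after`.
#' @export
lnc_expression_sets <- function(matrix_preactivation, matrix_postactivation,
                                threshold = 0.5, min_replicates = 2) {
  list(expressed_before = filter_expressed(matrix_preactivation, threshold,
                                           min_replicates),
       expressed_after = filter_expressed(matrix_postactivation, threshold,
                                          min_replicates))
}

#' Differentially expressed lncRNAs
#'
#' Intersection of the DE calls (FDR < `fdr_cut`, |log2 FC| > `fc_cut`) with
#' the post-activation expressed set (the RPKM > 0.5 filter).
#'
#' @param de_table lncRNA DE table data.frame.
#' @param expressed_after expressed lncRNA ids after activation.
#' @param fdr_cut,fc_cut DE cutoffs.
#' @return character vector of DE lncRNA ids.
#' @export
de_lncrnas <- function(de_table, expressed_after, fdr_cut = 0.05, fc_cut = 1.0) {
  intersect(unique(call_de(de_table, fdr_cut, fc_cut)$gene_id), expressed_after)
}

#' Biotype over/under-representation among DE lncRNAs
#'
#' For each biotype present in the expressed universe, hypergeometric tail
#' tests of its count among the DE set against the expressed set: `p_over =
#' P(X >= k)` and `p_under = P(X <= k)`.  Both tails are reported.
#'
#' @param de_set DE lncRNA ids (non-empty).
#' @param expressed_set expressed lncRNA ids (the universe).
#' @param ann annotation with a `biotype` column covering both sets.
#' @return data.frame (class rows of `LncClassStats`): `biotype`,
#'   `n_expressed`, `n_de`, `p_over`, `p_under`.
#' @export
biotype_representation <- function(de_set, expressed_set, ann) {
  de_set <- unique(de_set)
  expressed_set <- unique(expressed_set)
  if (length(de_set) == 0L) stop("empty query: no DE lncRNAs")
  if (!all(de_set %in% expressed_set))
    stop("DE set must be a subset of the expressed set")
  bt <- setNames(ann$biotype, ann$gene_id)
  if (any(!expressed_set %in% names(bt)))
    stop("expressed lncRNAs missing from the annotation")
  N <- length(expressed_set)
  n <- length(de_set)
  u_bt <- bt[expressed_set]
  rows <- lapply(sort(unique(u_bt)), function(b) {
    K <- sum(u_bt == b)
    k <- sum(bt[de_set] == b)
    data.frame(biotype = b, n_expressed = K, n_de = k,
               p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               p_under = phyper(k, K, N - K, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nearest protein-coding gene of a lncRNA
#'
#' Minimal interval distance on the same chromosome (0 if overlapping);
#' ties broken by the smaller start coordinate; strand is ignored.  Returns
#' `NULL` when no coding gene shares the chromosome.
#'
#' @param lnc lncRNA gene id (must be in the annotation).
#' @param ann annotation data.frame.
#' @param coding_biotypes biotype labels counted as protein-coding.
#' @return one-row data.frame `lnc`, `coding_gene`, `distance_bp`, or `NULL`.
#' @export
nearest_coding_gene <- function(lnc, ann,
                                coding_biotypes = c("coding", "protein_coding")) {
  row <- ann[ann$gene_id == lnc, , drop = FALSE]
  if (nrow(row) == 0L) stop(sprintf("lncRNA %s absent from annotation", lnc))
  cand <- ann[ann$chrom == row$chrom & ann$biotype %in% coding_biotypes &
              ann$gene_id != lnc, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  d <- pmax(0L, cand$start - row$end, row$start - cand$end)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.min(cand$start[best])]
  data.frame(lnc = lnc, coding_gene = cand$gene_id[best],
             distance_bp = d[best], stringsAsFactors = FALSE)
}

#' Most positively / negatively correlated coding genes per lncRNA
#'
#' Pearson correlation between each lncRNA profile and every coding DE
#' profile over the shared time points (profiles are replicate-averaged
#' log2(RPKM + 1)); per lncRNA the `top_n` strongest positive and negative
#' correlations are returned.  Constant profiles are excluded and flagged.
#'
#' @param lnc_profiles lncRNAs x timepoints numeric matrix.
#' @param coding_profiles coding genes x timepoints numeric matrix (same
#'   time grid).
#' @param top_n list length per direction (>= 1).
#' @return named list (one element per lncRNA): list with data.frames
#'   `positive` and `negative` (`gene`, `r`), plus attribute
#'   `excluded_constant` naming dropped profiles.
#' @export
top_correlated_coding <- function(lnc_profiles, coding_profiles, top_n = 5) {
  if (top_n < 1) stop("`top_n` must be >= 1")
  if (ncol(lnc_profiles) != ncol(coding_profiles))
    stop("profile matrices must share the time grid")
  const_l <- apply(lnc_profiles, 1L, sd) == 0
  const_c <- apply(coding_profiles, 1L, sd) == 0
  excluded <- c(rownames(lnc_profiles)[const_l], rownames(coding_profiles)[const_c])
  lncs <- lnc_profiles[!const_l, , drop = FALSE]
  cods <- coding_profiles[!const_c, , drop = FALSE]
  out <- lapply(rownames(lncs), function(id) {
    r <- apply(cods, 1L, function(p) cor(lncs[id, ], p))
    ord_pos <- order(-r, names(r))
    ord_neg <- order(r, names(r))
    kp <- head(ord_pos, top_n)
    kn <- head(ord_neg, top_n)
    list(positive = data.frame(gene = names(r)[kp], r = unname(r[kp]),
                               stringsAsFactors = FALSE),
         negative = data.frame(gene = names(r)[kn], r = unname(r[kn]),
                               stringsAsFactors = FALSE))
  })
  names(out) <- rownames(lncs)
  attr(out, "excluded_constant") <- excluded
  out
}
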