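# Chromosomal co-localization of a query gene set: clusters are maximal runs
# of query genes, in annotation order, in which each consecutive pair is
# separated by at most d non-query genes; empirical significance comes from
# permuting the query labels uniformly over the annotation's gene slots.

# Cluster sizes from per-chromosome query flags.  `flags` is a list (one
# logical vector per chromosome, genes in positional order).
coloc_cluster_sizes <- function(flags, d, min_size = 2) {
  sizes <- integer()
  for (f in flags) {
    idx <- which(f)
    if (length(idx) < min_size) next
    brk <- which(diff(idx) - 1L > d)
    runs <- diff(c(0L, brk, length(idx)))
    sizes <- c(sizes, runs[runs >= min_size])
  }
  sizes
}

ann_query_flags <- function(ann, query) {
  split(ann$gene_id %in% query, ann$chrom)
}

#' Find chromosomal clusters of a query gene set
#'
#' Genes are ordered by (chromosome, start); a cluster is a maximal run of
#' query genes in which every consecutive pair has at most `d` intervening
#' non-query genes; runs shorter than `min_size` are discarded.  The result
#' is invariant to the input ordering of `query`.
#'
#' @param query character vector of gene ids (subset of the annotation).
#' @param ann gene annotation data.frame.
#' @param d maximum intervening non-query genes between consecutive members
#'   (default 3).
#' @param min_size minimum cluster size (default 2).
#' @return data.frame with columns `chromosome`, `size`, `start`, `end`,
#'   `span_bp`, `members` (semicolon-joined, in positional order).
#' @export
find_clusters <- function(query, ann, d = 3, min_size = 2) {
  if (!all(query %in% ann$gene_id))
    stop("query genes must be a subset of the annotation")
  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), , drop = FALSE]
  rows <- list()
  for (cn in unique(ann$chrom)) {
    g <- ann[ann$chrom == cn, , drop = FALSE]
    idx <- which(g$gene_id %in% query)
    if (length(idx) < min_size) next
    brk <- which(diff(idx) - 1L > d)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(idx))
    for (j in seq_along(starts)) {
      run <- idx[starts[j]:ends[j]]
      if (length(run) < min_size) next
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = cn, size = length(run),
        start = g$start[run[1L]], end = g$end[run[length(run)]],
        span_bp = g$end[run[length(run)]] - g$start[run[1L]] + 1L,
        members = paste(g$gene_id[run], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chromosome = character(), size = integer(),
                      start = integer(), end = integer(), span_bp = integer(),
                      members = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Permutation p-values for co-localization
#'
#' Each permutation redistributes the `|query|` labels uniformly without
#' replacement over all annotation gene slots and recomputes the cluster
#' statistics.  Two statistics are reported: the global cluster count, and,
#' for each observed cluster size `s`, the number of clusters of size >= s.
#' Empirical p-values use the add-one estimator `(1 + #{perm >= obs}) /
#' (1 + n_perm)`, bounding them below by `1 / (1 + n_perm)`.
#'
#' @inheritParams find_clusters
#' @param n_perm number of permutations (>= 1; >= 100 for a 1e-2 reporting
#'   floor, default 1000).
#' @param seed integer seed.
#' @return list with `observed` (the [find_clusters()] table), `global`
#'   (list `statistic`, `p`) and `per_size` (data.frame `size`,
#'   `observed_count`, `p` for each observed size).
#' @export
permutation_pvalues <- function(query, ann, d = 3, n_perm = 1000, seed = 1,
                                min_size = 2) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  observed <- find_clusters(query, ann, d, min_size)
  obs_sizes <- observed$size
  obs_global <- nrow(observed)
  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), , drop = FALSE]
  n_genes <- nrow(ann)
  n_query <- length(unique(query))
  chrom_f <- factor(ann$chrom, levels = unique(ann$chrom))
  uniq_sizes <- sort(unique(obs_sizes))
  obs_ge <- vapply(uniq_sizes, function(s) sum(obs_sizes >= s), 0L)

  perm_stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(p) {
      lab <- logical(n_genes)
      lab[sample.int(n_genes, n_query)] <- TRUE
      sz <- coloc_cluster_sizes(split(lab, chrom_f), d, min_size)
      c(length(sz), vapply(uniq_sizes, function(s) sum(sz >= s), 0L))
    }, numeric(1L + length(uniq_sizes)))
  })
  perm_stats <- matrix(perm_stats, nrow = 1L + length(uniq_sizes))
  p_global <- (1 + sum(perm_stats[1L, ] >= obs_global)) / (1 + n_perm)
  p_size <- if (length(uniq_sizes))
    vapply(seq_along(uniq_sizes), function(i)
      (1 + sum(perm_stats[i + 1L, ] >= obs_ge[i])) / (1 + n_perm), 0)
  else numeric()
  list(observed = observed,
       global = list(statistic = obs_global, p = p_global),
       per_size = data.frame(size = uniq_sizes, observed_count = obs_ge,
                             p = p_size))
}

#' Export clusters in a circos-style text format
#'
#' One line per cluster: chromosome, start, end, cluster id -- suitable for
#' external track plotting.
#'
#' @param clusters data.frame from [find_clusters()].
#' @param path output file path.
#' @export
write_cluster_tracks <- function(clusters, path) {
  df <- data.frame(chromosome = clusters$chromosome, start = clusters$start,
                   end = clusters$end,
                   cluster_id = sprintf("cluster%03d", seq_len(nrow(clusters))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
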