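# Disease lead-SNP window linking and hypergeometric gene-set enrichment.

# Distance from a point to a 1-based inclusive interval (0 if inside).
point_interval_distance <- function(pos, start, end) {
  pmax(0L, start - pos, pos - end)
}

#' Link lead SNPs to genes by a genomic window
#'
#' Keeps SNPs with association p-value strictly below `p_cut` (default 1e-5)
#' and links a SNP to every gene on the same chromosome whose body
#' (start--end interval) lies within `window` bp (inclusive; distance 0 when
#' the SNP falls inside the gene).  Trait gene sets aggregate over all the
#' trait's SNPs.  SNPs on chromosomes absent from the annotation are skipped
#' with a warning.
#'
#' @param snps SNP data.frame (`snp_id`, `trait`, `chrom`, `pos`, `pvalue`).
#' @param ann gene annotation data.frame.
#' @param window linking window in bp (> 0), default 100 kb.
#' @param p_cut inclusion p-value cutoff (strict), default 1e-5.
#' @return named list trait -> character vector of linked gene ids, with
#'   attribute `n_skipped` (SNPs on unknown chromosomes).
#' @export
link_snps_to_genes <- function(snps, ann, window = 100000, p_cut = 1e-5) {
  if (window <= 0) stop("`window` must be positive")
  snps <- snps[snps$pvalue < p_cut, , drop = FALSE]
  unknown <- !snps$chrom %in% ann$chrom
  if (any(unknown))
    warning(sprintf("%d SNP(s) on chromosomes absent from the annotation were skipped",
                    sum(unknown)))
  snps <- snps[!unknown, , drop = FALSE]
  hits <- lapply(seq_len(nrow(snps)), function(i) {
    g <- ann[ann$chrom == snps$chrom[i], , drop = FALSE]
    d <- point_interval_distance(snps$pos[i], g$start, g$end)
    g$gene_id[d <= window]
  })
  traits <- split(hits, snps$trait)
  out <- lapply(traits, function(x) unique(unlist(x, use.names = FALSE)))
  out <- out[lengths(out) > 0]        # traits with no linked gene drop out
  attr(out, "n_skipped") <- sum(unknown)
  out
}

#' Hypergeometric over-representation test for gene sets
#'
#' For each term with at least `min_term_genes` genes in the universe,
#' computes the upper-tail probability `P(X >= k)` of drawing `k` term genes
#' in a query of size `n` from a universe of size `N` containing `K` term
#' genes, and adjusts across surviving terms by Benjamini-Hochberg.
#'
#' @param query character vector of query genes (must be in `universe`).
#' @param terms named list term -> gene vector; genes are intersected with
#'   the universe before testing.
#' @param universe character vector of background genes (non-empty).
#' @param min_term_genes minimum in-universe term size (default 2; smaller
#'   terms are dropped).
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`, `fdr`,
#'   `genes` (semicolon-joined overlap), sorted by `p`.
#' @export
hypergeom_enrich <- function(query, terms, universe, min_term_genes = 2) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), universe)
    K <- length(tg)
    if (K < min_term_genes) return(NULL)
    hit <- intersect(tg, query)
    k <- length(hit)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), c("term", "k", "K", "n", "N", "p", "fdr", "genes")]
  rownames(out) <- NULL
  out
}

#' Trait enrichment for several gene sets with set-specific universes
#'
#' Runs [hypergeom_enrich()] once per named gene set against the trait->gene
#' map, each with its own universe (e.g. all human genes for the human top
#' set, all orthologous genes for the common and mouse sets).  Gene sets
#' named in `mouse_sets` contain mouse ids and are translated to human ids
#' through the ortholog map first (SNP-trait links are defined on human
#' genes); mouse genes without an ortholog are dropped and counted.
#'
#' @param gene_sets named list of character vectors.
#' @param trait_map named list trait -> gene vector (human gene ids), e.g.
#'   from [link_snps_to_genes()].
#' @param universes named list of universes, same names as `gene_sets`.
#' @param ortho ortholog map (needed when `mouse_sets` is non-empty).
#' @param mouse_sets names of the sets given in mouse ids.
#' @param min_term_genes minimum trait size, as in [hypergeom_enrich()].
#' @return named list of enrichment data.frames; each carries an attribute
#'   `n_unmapped` (mouse genes dropped for lack of an ortholog).
#' @export
enrich_gene_sets_vs_traits <- function(gene_sets, trait_map, universes,
                                       ortho = NULL, mouse_sets = character(),
                                       min_term_genes = 2) {
  stopifnot(all(names(gene_sets) %in% names(universes)))
  lapply(setNames(names(gene_sets), names(gene_sets)), function(nm) {
    q <- gene_sets[[nm]]
    u <- universes[[nm]]
    unmapped <- 0L
    if (nm %in% mouse_sets) {
      if (is.null(ortho)) stop("`ortho` required to map mouse gene sets")
      map <- setNames(ortho$human_gene, ortho$mouse_gene)
      unmapped <- sum(!q %in% names(map))
      q <- unname(map[intersect(q, names(map))])
      u <- unname(map[intersect(u, names(map))])
    }
    res <- hypergeom_enrich(q, trait_map, u, min_term_genes)
    attr(res, "n_unmapped") <- unmapped
    res
  })
}
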