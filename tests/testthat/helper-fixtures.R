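# Shared fixtures, built in code at test time.

paper_timepoints <- c(0, 0.5, 1, 2, 4, 6, 12, 24, 48, 72)

# Minimal TimeCourseMatrix from a genes x (timepoints * reps) value matrix.
toy_tc <- function(values, timepoints, n_replicates = 3, species = "human") {
  time_course_matrix(values, timepoints, n_replicates, species = species)
}

# A tiny uniform annotation: `n` genes per chromosome, regular spacing.
toy_annotation <- function(n_chrom = 1, n_genes = 10, gene_length = 1000,
                           spacing = 50000, biotypes = "coding") {
  simulate_genome_annotation(n_chrom, n_genes, gene_length, spacing,
                             biotype_fractions = setNames(
                               rep(1 / length(biotypes), length(biotypes)),
                               biotypes),
                             seed = 42)
}

# Exhaustive hypergeometric upper-tail oracle: enumerate all C(N, n) draws.
hyper_upper_oracle <- function(k, K, N, n) {
  universe <- seq_len(N)
  term <- seq_len(K)
  draws <- combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% term))
  mean(hits >= k)
}

# Brute-force Ward merging via Lance-Williams updates on squared Euclidean
# distances; returns the merge list in hclust's encoding.
ward_merge_oracle <- function(mat) {
  n <- nrow(mat)
  d2 <- as.matrix(dist(mat))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  labels <- -seq_len(n)          # hclust convention: negatives are leaves
  merges <- matrix(0L, n - 1L, 2L)
  for (step in seq_len(n - 1L)) {
    # after Lance-Williams updates the stored d2 values ARE the (scaled)
    # Ward merge costs, so the next merge is the smallest updated d2
    best <- c(NA, NA); bw <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      a <- active[i]; b <- active[j]
      if (d2[a, b] < bw) { bw <- d2[a, b]; best <- c(b, a) }
    }
    a <- best[1L]; b <- best[2L]
    merges[step, ] <- sort(c(labels[a], labels[b]))
    # Lance-Williams update of squared distances for the Ward criterion
    for (c_ in setdiff(active, c(a, b))) {
      sab <- sizes[a] + sizes[b] + sizes[c_]
      d2[a, c_] <- d2[c_, a] <-
        ((sizes[a] + sizes[c_]) * d2[a, c_] +
         (sizes[b] + sizes[c_]) * d2[b, c_] -
         sizes[c_] * d2[a, b]) / sab
    }
    sizes[a] <- sizes[a] + sizes[b]
    labels[a] <- step
    active <- setdiff(active, b)
  }
  merges
}
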