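test_that("expression filter applies the two-replicate rule per time point", {
  # gene passing at a single time point with exactly two replicates at the
  # threshold is kept; a gene never reaching two replicates is dropped
  vals <- rbind(
    pass_boundary = c(3, 3, 0, 0, 0, 0),
    one_rep_only  = c(5, 0, 0, 5, 0, 0),
    all_high      = c(4, 4, 4, 4, 4, 4))
  tc <- toy_tc(vals, c(0, 24))
  kept <- filter_expressed(tc, 3)
  expect_setequal(kept, c("pass_boundary", "all_high"))
  # lncRNA threshold has the same semantics
  kept_lnc <- filter_expressed(toy_tc(vals / 6, c(0, 24)), 0.5)
  expect_setequal(kept_lnc, c("pass_boundary", "all_high"))
  expect_error(filter_expressed(tc, 3, min_replicates = 4), "exceeds")
  expect_error(filter_expressed(tc, 0), "positive")
})

test_that("DE calling uses strict inequalities on both cutoffs", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   timepoint = 24,
                   log2_fc = c(2, 1.0, -1.5, 1.2),
                   fdr = c(0.05, 0.01, 0.01, 0.04))
  out <- call_de(de)
  expect_setequal(out$gene_id, c("c", "d"))
  expect_equal(out$direction[out$gene_id == "c"], "down")
  expect_equal(out$direction[out$gene_id == "d"], "up")
})

test_that("top-20% ranking applies the ceiling rule and gene-id tie-break", {
  up <- data.frame(gene_id = sprintf("u%02d", 1:10), timepoint = 4,
                   log2_fc = seq(0.4, 4.0, length.out = 10), fdr = 0.01)
  down <- data.frame(gene_id = sprintf("d%02d", 1:7), timepoint = 4,
                     log2_fc = -seq(0.5, 3.5, by = 0.5), fdr = 0.01)
  r <- rank_top20(rbind(up, down), 4)
  expect_equal(r$up, c("u10", "u09"))          # ceiling(0.2 * 10) = 2
  expect_equal(r$down, c("d07", "d06"))        # ceiling(0.2 * 7) = 2
  # all FDR >= 0.05: both lists empty
  none <- rank_top20(transform(up, fdr = 0.05), 4)
  expect_equal(lengths(none), c(up = 0L, down = 0L))
  # ties broken by gene id ascending
  tie <- data.frame(gene_id = c("b", "a", "c"), timepoint = 4,
                    log2_fc = c(2, 2, 2), fdr = 0.01)
  expect_equal(rank_top20(tie, 4)$up, "a")
  # |log2 FC| below the 0.3 floor is not a candidate
  floor_tab <- data.frame(gene_id = c("x", "y"), timepoint = 4,
                          log2_fc = c(0.29, 0.3), fdr = 0.01)
  expect_equal(rank_top20(floor_tab, 4)$up, "y")
})

test_that("ranking output size is exactly the ceiling and grows monotonically", {
  set.seed(31)
  for (n in c(1, 3, 5, 9, 20)) {
    tab <- data.frame(gene_id = sprintf("g%02d", 1:n), timepoint = 2,
                      log2_fc = runif(n, 0.4, 3), fdr = 0.01)
    expect_length(rank_top20(tab, 2)$up, ceiling(0.2 * n))
  }
  small <- data.frame(gene_id = sprintf("g%02d", 1:9), timepoint = 2,
                      log2_fc = runif(9, 0.4, 3), fdr = 0.01)
  bigger <- rbind(small, data.frame(gene_id = "g99", timepoint = 2,
                                    log2_fc = 5, fdr = 0.001))
  expect_gte(length(rank_top20(bigger, 2)$up), length(rank_top20(small, 2)$up))
})

test_that("concordance merges time points and respects direction", {
  de_h <- data.frame(gene_id = c("h1", "h2"), timepoint = c(4, 4),
                     log2_fc = c(2, 2), fdr = 0.01)
  de_m <- data.frame(gene_id = c("m1", "m2"), timepoint = c(72, 72),
                     log2_fc = c(2, -2), fdr = 0.01)
  ortho <- data.frame(human_gene = c("h1", "h2"), mouse_gene = c("m1", "m2"))
  rs_h <- ranked_sets(de_h)
  rs_m <- ranked_sets(de_m)
  conc <- concordant_pairs(rs_h, rs_m, ortho)
  # h1 up at 4 h, m1 up at 72 h: concordant through merged sets
  expect_equal(conc$human_gene, "h1")
  # h2 up vs m2 down: not concordant
  expect_false("h2" %in% conc$human_gene)
  empty <- concordant_pairs(rs_h, ranked_sets(transform(de_m, fdr = 0.9)), ortho)
  expect_equal(nrow(empty), 0L)
})

test_that("identical profiles always co-cluster", {
  sim <- simulate_ortholog_timecourse(40, frac_shared = 1, frac_shifted = 0,
                                      noise_sd = 0, seed = 17)
  cl <- cluster_profiles_kmeans(sim$human, sim$mouse,
                                rownames(sim$human$values),
                                rownames(sim$mouse$values),
                                sim$orthologs, k = 10, restarts = 5, seed = 1)
  # zero noise: each pair's profiles are identical points in profile space
  expect_equal(nrow(cl$pairs), 40L)
  cl2 <- cluster_profiles_kmeans(sim$human, sim$mouse,
                                 rownames(sim$human$values),
                                 rownames(sim$mouse$values),
                                 sim$orthologs, k = 10, restarts = 5, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)
  expect_error(cluster_profiles_kmeans(sim$human, sim$mouse,
                                       rownames(sim$human$values)[1:3],
                                       rownames(sim$mouse$values)[1:3],
                                       sim$orthologs, k = 10),
               "fewer pooled genes")
})

test_that("hierarchical leaf order agrees with brute-force Ward merging", {
  set.seed(23)
  mat <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("r", 1:6), NULL))
  ord <- hierarchical_order(mat)
  expect_setequal(ord, rownames(mat))
  hc <- hclust(dist(mat), method = "ward.D2")
  oracle <- ward_merge_oracle(mat)
  expect_equal(unname(t(apply(hc$merge, 1, sort))), unname(oracle))
  # identical rows merge first
  mat2 <- rbind(mat, r7 = mat["r1", ])
  hc2 <- hclust(dist(mat2), method = "ward.D2")
  expect_setequal(abs(hc2$merge[1, ]), c(1, 7))
  expect_error(hierarchical_order(rbind(mat, c(NaN, 1, 2, 3))), "non-finite")
})

test_that("ortholog expression correlation matches the textbook formula", {
  sim <- simulate_ortholog_timecourse(5, frac_shared = 1, frac_shifted = 0,
                                      noise_sd = 0, seed = 19)
  pairs <- sim$orthologs
  res <- correlate_ortholog_expression(sim$human, sim$mouse, pairs)
  expect_equal(res$r, rep(1, 5), tolerance = 1e-12)
  # direct covariance-formula oracle on noisy pairs
  sim2 <- simulate_ortholog_timecourse(5, frac_shared = 1, frac_shifted = 0,
                                       noise_sd = 0.5, seed = 20)
  res2 <- correlate_ortholog_expression(sim2$human, sim2$mouse, sim2$orthologs)
  ph <- profile_matrix(sim2$human)
  pm <- profile_matrix(sim2$mouse)
  for (i in 1:5) {
    a <- ph[i, ]; b <- pm[i, ]
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(res2$r[i], oracle, tolerance = 1e-12)
  }
  # negated profile correlates at exactly -1
  neg <- sim$mouse
  neg$values <- 2^(2 * log2(mean(neg$values + 1)) - log2(neg$values + 1)) - 1
  resn <- correlate_ortholog_expression(sim$human, neg, pairs)
  expect_equal(resn$r, rep(-1, 5), tolerance = 1e-10)
})
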