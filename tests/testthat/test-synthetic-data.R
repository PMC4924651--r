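test_that("zero-noise shared pairs have identical replicate-mean profiles", {
  sim <- simulate_ortholog_timecourse(10, frac_shared = 1, frac_shifted = 0,
                                      noise_sd = 0, seed = 7)
  mh <- profile_matrix(sim$human)
  mm <- profile_matrix(sim$mouse)
  expect_equal(unname(mh), unname(mm), tolerance = 1e-12)
})

test_that("class counts follow the requested fractions", {
  sim <- simulate_ortholog_timecourse(100, frac_shared = 0.5,
                                      frac_shifted = 0.25,
                                      shift_set = c(6, 12), seed = 1)
  counts <- table(sim$truth$class)
  expect_equal(unname(counts[c("shared", "shifted", "divergent")]),
               c(50L, 25L, 25L), ignore_attr = TRUE)
  expect_true(all(sim$truth$true_shift_hours[sim$truth$class == "shared"] == 0))
  expect_true(all(sim$truth$human_gene %in% rownames(sim$human$values)))
  expect_true(all(sim$truth$mouse_gene %in% rownames(sim$mouse$values)))
  expect_equal(sim$truth$human_gene, sim$orthologs$human_gene)
})

test_that("generators are pure functions of their seed", {
  a <- simulate_ortholog_timecourse(20, seed = 1)
  b <- simulate_ortholog_timecourse(20, seed = 1)
  expect_identical(a, b)
  c <- simulate_ortholog_timecourse(20, seed = 2)
  expect_false(identical(a$human$values, c$human$values))

  expect_identical(simulate_de_tables(30, c(24, 72), seed = 5),
                   simulate_de_tables(30, c(24, 72), seed = 5))
  ann <- toy_annotation(2, 20)
  expect_identical(
    simulate_snp_catalog(ann, "T1", list(T1 = ann$gene_id[1:3]), seed = 3),
    simulate_snp_catalog(ann, "T1", list(T1 = ann$gene_id[1:3]), seed = 3))
})

test_that("shifted pairs evaluate the human latent curve at t + shift", {
  sim <- simulate_ortholog_timecourse(8, frac_shared = 0, frac_shifted = 1,
                                      shift_set = c(12), noise_sd = 0, seed = 3,
                                      timepoints = c(0, 12, 24, 36, 48, 60))
  # mouse value at t must equal human latent at t + 12; compare mouse at
  # t = 0..48 against human at t = 12..60 (grid alignment makes this exact)
  mh <- profile_matrix(sim$human)
  mm <- profile_matrix(sim$mouse)
  expect_equal(unname(mm[, 1:5]), unname(mh[, 2:6]), tolerance = 1e-10)
})

test_that("planted DE rows pass the cutoffs and nulls stay below them", {
  planted <- list("72" = data.frame(gene = sprintf("g%04d", 1:10),
                                    direction = "up", log2fc = 1:10))
  de <- simulate_de_tables(50, c(24, 72), planted, seed = 2)
  hit <- de[de$timepoint == 72 & de$gene_id %in% sprintf("g%04d", 1:10), ]
  expect_true(all(hit$fdr < 0.05))
  expect_equal(sort(hit$log2_fc), as.numeric(1:10))

  null_de <- simulate_de_tables(200, c(24, 72), seed = 4)
  pass <- null_de$fdr < 0.05 & abs(null_de$log2_fc) >= 0.3
  expect_equal(sum(pass), 0L)
  expect_error(simulate_de_tables(5, 24, list("24" = data.frame(
    gene = "g0009", direction = "up", log2fc = 2))), "universe")
})

test_that("genome annotation layout is regular and biotype fractions exact", {
  ann <- simulate_genome_annotation(1, 10, gene_length = 1000, spacing = 50000)
  expect_equal(ann$start, 1L + (0:9) * 51000L)
  expect_equal(ann$end - ann$start + 1L, rep(1000L, 10))

  ann2 <- simulate_genome_annotation(2, 10, biotype_fractions = c(coding = 1))
  expect_true(all(ann2$biotype == "coding"))
  ann3 <- simulate_genome_annotation(
    1, 10, biotype_fractions = c(coding = 0.5, lincRNA = 0.3, antisense = 0.2))
  expect_equal(unname(table(ann3$biotype)[c("coding", "lincRNA", "antisense")]),
               c(5L, 3L, 2L), ignore_attr = TRUE)
  expect_error(simulate_genome_annotation(1, 10,
                                          biotype_fractions = c(coding = 0.7)),
               "sum to 1")
  expect_error(simulate_genome_annotation(1, 10, spacing = 0), "positive")
})

test_that("planted SNPs land inside the window of their target genes", {
  ann <- toy_annotation(2, 30)
  targets <- ann$gene_id[c(1, 5, 9)]
  snps <- simulate_snp_catalog(ann, "T1", list(T1 = targets),
                               snps_per_trait = 20, window = 100000, seed = 8)
  expect_true(all(snps$pvalue < 1e-5))
  tg <- ann[ann$gene_id %in% targets, ]
  ok <- vapply(seq_len(nrow(snps)), function(i) {
    same <- tg[tg$chrom == snps$chrom[i], ]
    any(pmax(0, same$start - snps$pos[i], snps$pos[i] - same$end) <= 100000)
  }, TRUE)
  expect_true(all(ok))

  none <- simulate_snp_catalog(ann, "T1", list(T1 = targets),
                               snps_per_trait = 0, seed = 8)
  expect_false("T1" %in% none$trait)
  expect_error(simulate_snp_catalog(ann, "T1", list(T1 = targets),
                                    window = 0), "positive")
})
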