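# Synthetic inputs with planted ground truth.  Latent expression profiles are
# smooth random functions: 2-3 random-phase sinusoids with periods >= 24 h
# plus a sigmoid trend, standardized to zero mean / unit variance on the
# sampled grid so that noise_sd is interpreted on the standardized log scale.
# Expression matrices are built on the log2 scale and exponentiated, so the
# pipeline's own log2(RPKM + 1) transform recovers the latent structure.

# Returns a closure f(t) (t in hours, defined for all real t); standardization
# constants are computed on the reference grid.
make_latent_curve <- function(grid_hours) {
  n_sin <- sample(2:3, 1L)
  # periods well above the widest sampling interval (24 h), so the latent
  # kinetics are resolvable on the 0-72 h design rather than aliased
  periods <- runif(n_sin, 48, 120)
  phases <- runif(n_sin, 0, 2 * pi)
  amps <- runif(n_sin, 0.5, 1)
  t0 <- runif(1, 4, 48)
  sl <- runif(1, 2, 12)
  a_sig <- runif(1, -1.5, 1.5)
  raw <- function(t) {
    s <- a_sig / (1 + exp(-(t - t0) / sl))
    for (j in seq_len(n_sin))
      s <- s + amps[j] * sin(2 * pi * t / periods[j] + phases[j])
    s
  }
  g <- raw(grid_hours)
  mu <- mean(g)
  sdev <- sd(g)
  if (!is.finite(sdev) || sdev < 1e-8) sdev <- 1
  function(t) (raw(t) - mu) / sdev
}

#' Simulate a two-species ortholog expression time course
#'
#' Generates replicated RPKM time-course matrices for two species with a
#' planted mixture of ortholog classes: `shared` pairs draw both species'
#' values from one latent curve, `shifted` pairs evaluate the second species'
#' curve at `t + true_shift_hours`, and `divergent` pairs use two independent
#' latent curves.  Log2 expression is `baseline + amplitude * (latent +
#' noise)`, with i.i.d. Gaussian noise per replicate observation on the
#' standardized scale, then exponentiated to RPKM.
#'
#' Class counts are deterministic: `round(frac_shared * n_pairs)` shared,
#' `round(frac_shifted * n_pairs)` shifted (shifts cycled through
#' `shift_set`), remainder divergent.
#'
#' @param n_pairs number of ortholog pairs (> 0).
#' @param frac_shared,frac_shifted class fractions in \[0, 1\] with
#'   `frac_shared + frac_shifted <= 1`.
#' @param shift_set hours (each in \[-24, 24\]) cycled over the shifted pairs.
#' @param noise_sd replicate noise SD on the standardized log scale.
#' @param n_replicates replicates per time point.
#' @param timepoints strictly increasing hours.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param baseline,amplitude location/scale placing latent curves on the log2
#'   RPKM scale.
#' @return list with elements `human` and `mouse` (`TimeCourseMatrix`),
#'   `orthologs` (data.frame human_gene/mouse_gene) and `truth` (data.frame
#'   pair_id, human_gene, mouse_gene, class, true_shift_hours,
#'   base_profile_id).
#' @export
simulate_ortholog_timecourse <- function(n_pairs,
                                         frac_shared = 0.5,
                                         frac_shifted = 0.25,
                                         shift_set = c(-12, -6, 6, 12),
                                         noise_sd = 0.2,
                                         n_replicates = 3,
                                         timepoints = c(0, 0.5, 1, 2, 4, 6, 12, 24, 48, 72),
                                         seed = 1,
                                         baseline = 6,
                                         amplitude = 1.5) {
  if (!is.numeric(n_pairs) || n_pairs <= 0) stop("`n_pairs` must be positive")
  if (length(timepoints) == 0L) stop("`timepoints` must be non-empty")
  if (frac_shared < 0 || frac_shared > 1 || frac_shifted < 0 || frac_shifted > 1 ||
      frac_shared + frac_shifted > 1 + 1e-12)
    stop("fractions must lie in [0, 1] with frac_shared + frac_shifted <= 1")
  if (any(abs(shift_set) > 24)) stop("`shift_set` must lie within [-24, 24] hours")
  n_pairs <- as.integer(n_pairs)
  n_shared <- as.integer(round(frac_shared * n_pairs))
  n_shifted <- as.integer(round(frac_shifted * n_pairs))
  if (n_shared + n_shifted > n_pairs) n_shifted <- n_pairs - n_shared
  n_div <- n_pairs - n_shared - n_shifted

  withr::with_seed(as.integer(seed), {
    classes <- c(rep("shared", n_shared), rep("shifted", n_shifted),
                 rep("divergent", n_div))
    shifts <- numeric(n_pairs)
    if (n_shifted > 0L)
      shifts[classes == "shifted"] <-
        rep_len(shift_set, n_shifted)
    pair_id <- sprintf("pair%04d", seq_len(n_pairs))
    hg <- sprintf("HG%04d", seq_len(n_pairs))
    mg <- sprintf("MG%04d", seq_len(n_pairs))
    n_tp <- length(timepoints)
    n_col <- n_tp * n_replicates
    vh <- matrix(0, n_pairs, n_col, dimnames = list(hg, NULL))
    vm <- matrix(0, n_pairs, n_col, dimnames = list(mg, NULL))
    t_rep <- rep(timepoints, each = n_replicates)
    for (i in seq_len(n_pairs)) {
      fh <- make_latent_curve(timepoints)
      fm <- if (classes[i] == "divergent") make_latent_curve(timepoints)
            else function(t) fh(t + shifts[i])
      zh <- baseline + amplitude * (fh(t_rep) + rnorm(n_col, sd = noise_sd))
      zm <- baseline + amplitude * (fm(t_rep) + rnorm(n_col, sd = noise_sd))
      vh[i, ] <- pmax(2^zh - 1, 0)
      vm[i, ] <- pmax(2^zm - 1, 0)
    }
    list(
      human = time_course_matrix(vh, timepoints, n_replicates,
                                 species = "human", condition = "Th17"),
      mouse = time_course_matrix(vm, timepoints, n_replicates,
                                 species = "mouse", condition = "Th17"),
      orthologs = data.frame(human_gene = hg, mouse_gene = mg,
                             stringsAsFactors = FALSE),
      truth = data.frame(pair_id = pair_id, human_gene = hg, mouse_gene = mg,
                         class = classes, true_shift_hours = shifts,
                         base_profile_id = sprintf("profile%04d", seq_len(n_pairs)),
                         stringsAsFactors = FALSE))
  })
}

#' Simulate a per-time-point differential-expression table
#'
#' One row per (gene, time point).  Planted hits receive FDR < 0.05 and their
#' stated log2 fold change (sign from `direction`); null rows draw FDR from
#' `null_fdr_range` and log2 FC from N(0, 0.1), keeping them below both the
#' DE cutoffs (FDR < 0.05, |log2 FC| > 1) and the ranking floor (0.3) with
#' high probability.
#'
#' @param n_genes number of genes (ids `g0001`, ...).
#' @param timepoints hours at which DE was tested.
#' @param planted_top named list keyed by `as.character(timepoint)`; each
#'   element a data.frame with columns `gene`, `direction` ("up"/"down") and
#'   `log2fc` (positive magnitude).
#' @param null_fdr_range interval the null FDRs are drawn from.
#' @param seed integer seed.
#' @param genes optional explicit gene ids (length `n_genes`); defaults to
#'   `g0001`, `g0002`, ...
#' @return data.frame with columns `gene_id`, `timepoint`, `log2_fc`, `fdr`.
#' @export
simulate_de_tables <- function(n_genes, timepoints, planted_top = list(),
                               null_fdr_range = c(0.05, 1), seed = 1,
                               genes = NULL) {
  if (n_genes <= 0) stop("`n_genes` must be positive")
  genes <- genes %||% sprintf("g%04d", seq_len(n_genes))
  if (length(genes) != n_genes) stop("`genes` must have length `n_genes`")
  for (tp in names(planted_top)) {
    p <- planted_top[[tp]]
    if (anyDuplicated(p$gene))
      stop(sprintf("duplicate planted gene at timepoint %s", tp))
    if (!all(p$gene %in% genes))
      stop("planted genes must belong to the simulated gene universe")
  }
  withr::with_seed(as.integer(seed), {
    de <- do.call(rbind, lapply(timepoints, function(tp) {
      fdr <- runif(n_genes, null_fdr_range[1L], null_fdr_range[2L])
      fc <- rnorm(n_genes, 0, 0.1)
      p <- planted_top[[as.character(tp)]]
      if (!is.null(p) && nrow(p)) {
        idx <- match(p$gene, genes)
        fdr[idx] <- runif(nrow(p), 1e-8, 0.049)
        fc[idx] <- ifelse(p$direction == "up", 1, -1) * abs(p$log2fc)
      }
      data.frame(gene_id = genes, timepoint = tp, log2_fc = fc, fdr = fdr,
                 stringsAsFactors = FALSE)
    }))
    rownames(de) <- NULL
    de
  })
}

#' Simulate a multi-chromosome gene annotation
#'
#' Non-overlapping genes laid out at regular spacing: gene `i` on each
#' chromosome starts at `1 + (i - 1) * (gene_length + spacing)` (1-based
#' inclusive).  Biotypes are assigned in the exact proportions of
#' `biotype_fractions` (largest-remainder rounding) and shuffled across genes.
#'
#' @param n_chromosomes,genes_per_chromosome layout counts.
#' @param gene_length,spacing gene span and intergenic gap in bp (spacing > 0).
#' @param biotype_fractions named numeric vector summing to 1.
#' @param seed integer seed (biotype shuffle and strand assignment).
#' @return annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`), sorted by (chrom, start).
#' @export
simulate_genome_annotation <- function(n_chromosomes, genes_per_chromosome,
                                       gene_length = 1000, spacing = 50000,
                                       biotype_fractions = c(coding = 1),
                                       seed = 1) {
  if (spacing <= 0) stop("`spacing` must be positive")
  if (abs(sum(biotype_fractions) - 1) > 1e-8)
    stop("`biotype_fractions` must sum to 1")
  n <- n_chromosomes * genes_per_chromosome
  # largest-remainder apportionment of biotype counts
  exact <- biotype_fractions * n
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  withr::with_seed(as.integer(seed), {
    biotypes <- sample(rep(names(biotype_fractions), counts))
    i <- rep(seq_len(genes_per_chromosome), times = n_chromosomes)
    chrom <- rep(as.character(seq_len(n_chromosomes)), each = genes_per_chromosome)
    start <- 1 + (i - 1) * (gene_length + spacing)
    ann <- data.frame(
      gene_id = sprintf("g%s_%04d", chrom, i),
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + gene_length - 1),
      strand = sample(c("+", "-"), n, replace = TRUE),
      biotype = biotypes, stringsAsFactors = FALSE)
    validate_annotation(ann, "simulate_genome_annotation")
  })
}

#' Simulate a disease lead-SNP catalog
#'
#' Planted SNPs for each trait are placed uniformly within `window` bp of a
#' randomly chosen target gene from `planted[[trait]]`, with association
#' p-values strictly below 1e-5.  Background SNPs (trait label
#' `"background"`) are placed uniformly across the genome, also with
#' p < 1e-5, emulating catalog SNPs unrelated to the planted gene sets.
#'
#' @param annotation gene annotation data.frame.
#' @param traits trait labels.
#' @param planted named list trait -> target gene ids (must exist in
#'   `annotation`).
#' @param snps_per_trait SNPs planted per trait (0 drops the trait).
#' @param window placement window in bp (> 0).
#' @param background_snps number of background SNPs.
#' @param seed integer seed.
#' @return SNP data.frame (`snp_id`, `trait`, `chrom`, `pos`, `pvalue`).
#' @export
simulate_snp_catalog <- function(annotation, traits, planted,
                                 snps_per_trait = 5, window = 100000,
                                 background_snps = 0, seed = 1) {
  if (window <= 0) stop("`window` must be positive")
  planted_genes <- unique(unlist(planted))
  if (!all(planted_genes %in% annotation$gene_id))
    stop("planted genes must exist in the annotation")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (trait in traits) {
      if (snps_per_trait == 0L) next
      targets <- annotation[annotation$gene_id %in% planted[[trait]], , drop = FALSE]
      if (nrow(targets) == 0L) next
      g <- targets[sample.int(nrow(targets), snps_per_trait, replace = TRUE), , drop = FALSE]
      pos <- vapply(seq_len(nrow(g)), function(j)
        sample(seq(max(1L, g$start[j] - window), g$end[j] + window), 1L), 1)
      rows[[trait]] <- data.frame(
        snp_id = sprintf("snp_%s_%03d", gsub("[^A-Za-z0-9]", "", trait),
                         seq_len(snps_per_trait)),
        trait = trait, chrom = g$chrom, pos = as.integer(pos),
        pvalue = 10^runif(snps_per_trait, -12, -5.05),
        stringsAsFactors = FALSE)
    }
    if (background_snps > 0) {
      chrom_max <- tapply(annotation$end, annotation$chrom, max)
      bg_chrom <- sample(names(chrom_max), background_snps, replace = TRUE)
      bg_pos <- vapply(bg_chrom, function(cn) sample.int(chrom_max[[cn]], 1L), 1L)
      rows[["background"]] <- data.frame(
        snp_id = sprintf("snp_bg_%04d", seq_len(background_snps)),
        trait = "background", chrom = bg_chrom, pos = as.integer(bg_pos),
        pvalue = 10^runif(background_snps, -12, -5.05),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(snp_id = character(), trait = character(),
                        chrom = character(), pos = integer(),
                        pvalue = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
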