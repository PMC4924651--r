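# End-to-end pipeline driver.  A single config (R list or YAML file) names
# the inputs, toggles stages and carries the numeric parameters, whose
# defaults are the analysis' canonical values (FDR 0.05, |log2 FC| > 1,
# ranking floor 0.3, top fraction 0.2, k = 30, 100 kb SNP window, SNP
# p < 1e-5, co-localization d <= 3, BF threshold 10, time shift within
# +/-24 h, RPKM filters 3 / 0.5).  One global seed fans out into per-stage
# seeds through derive_seed(), so toggling a stage never perturbs another
# stage's random stream.

pipeline_defaults <- function() {
  list(
    seed = 1,
    out_dir = "orthokinetics_results",
    stages = list(simulate = TRUE, filter = TRUE, rank = TRUE,
                  concord = TRUE, gp = TRUE, cluster = TRUE,
                  enrich = TRUE, coloc = TRUE, lncrna = TRUE),
    inputs = list(expression_human = NULL, expression_mouse = NULL,
                  de_human = NULL, de_mouse = NULL, orthologs = NULL,
                  annotation = NULL, snps = NULL, terms = NULL,
                  lnc_expression = NULL, lnc_de = NULL),
    params = list(fdr = 0.05, fc = 1.0, fc_floor = 0.3, fraction = 0.2,
                  k = 30, window = 100000, snp_p = 1e-5, d = 3,
                  bf_threshold = 10, dt_step = 2, dt_max = 24,
                  rpkm_coding = 3, rpkm_lnc = 0.5, n_perm = 1000,
                  kmeans_restarts = 10, gp_restarts = 2, gp_max_pairs = Inf),
    sim = list(n_pairs = 40, frac_shared = 0.5, frac_shifted = 0.25,
               noise_sd = 0.2, n_replicates = 3,
               timepoints = c(0, 0.5, 1, 2, 4, 6, 12, 24, 48, 72),
               n_lnc = 60, n_chromosomes = 3, genes_per_chromosome = 80))
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, "$", nm)
    if (!nm %in% names(defaults))
      stop(sprintf("unknown config key: %s", full))
    if (is.list(defaults[[nm]]) && !is.null(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    else
      defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and overrides them with the
#' caller-supplied values; unknown keys are rejected rather than silently
#' ignored.  The configuration round-trips through YAML.
#'
#' @param ... named top-level sections (`seed`, `out_dir`, `stages`,
#'   `inputs`, `params`, `sim`) as lists or scalars.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(pipeline_defaults(), user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  p <- cfg$params
  stopifnot(p$fdr > 0, p$fdr < 1, p$fc >= 0, p$fc_floor >= 0,
            p$fraction > 0, p$fraction <= 1, p$k >= 2, p$window > 0,
            p$snp_p > 0, p$d >= 0, p$bf_threshold > 0, p$dt_step > 0,
            p$dt_max > 0, p$dt_max <= 24, p$rpkm_coding > 0, p$rpkm_lnc > 0,
            p$n_perm >= 1)
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a validated `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  validate_config(merge_config(pipeline_defaults(), user))
}

#' @rdname read_pipeline_config
#' @param config a `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

tsv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Generate every pipeline input with planted ground truth and write the TSVs.
simulate_stage <- function(cfg, dir) {
  s <- cfg$sim
  seed <- derive_seed(cfg$seed, "simulate")
  sim <- simulate_ortholog_timecourse(
    n_pairs = s$n_pairs, frac_shared = s$frac_shared,
    frac_shifted = s$frac_shifted, noise_sd = s$noise_sd,
    n_replicates = s$n_replicates, timepoints = s$timepoints,
    seed = seed)
  hg <- sim$truth$human_gene
  mg <- sim$truth$mouse_gene
  tps <- s$timepoints

  # plant concordant DE: the shared pairs become DE in both species, split
  # between up and down, at late time points
  shared <- sim$truth$class == "shared"
  n_pl <- sum(shared)
  dir_pl <- rep(c("up", "down"), length.out = n_pl)
  fc_pl <- seq(1.2, 3, length.out = max(n_pl, 2))[seq_len(n_pl)]
  plant <- function(genes) {
    tp_pick <- rep(c(24, 72), length.out = n_pl)
    out <- list()
    for (tp in unique(tp_pick)) {
      i <- tp_pick == tp
      out[[as.character(tp)]] <- data.frame(gene = genes[i],
                                            direction = dir_pl[i],
                                            log2fc = fc_pl[i],
                                            stringsAsFactors = FALSE)
    }
    out
  }
  de_h <- simulate_de_tables(s$n_pairs, tps, plant(hg[shared]),
                             seed = derive_seed(seed, "de_h"), genes = hg)
  de_m <- simulate_de_tables(s$n_pairs, tps, plant(mg[shared]),
                             seed = derive_seed(seed, "de_m"), genes = mg)

  # genome annotation hosting the human genes, lncRNAs and filler genes,
  # with a planted run of adjacent DE genes for the co-localization stage
  n_slots <- s$n_chromosomes * s$genes_per_chromosome
  n_lnc <- s$n_lnc
  if (n_slots < s$n_pairs + n_lnc)
    stop("annotation too small for the simulated genes; increase genes_per_chromosome")
  ann <- simulate_genome_annotation(
    s$n_chromosomes, s$genes_per_chromosome,
    biotype_fractions = c(coding = 1), seed = derive_seed(seed, "ann"))
  lnc_ids <- sprintf("LNC%04d", seq_len(n_lnc))
  ids <- ann$gene_id
  planted_run <- hg[shared][seq_len(min(5, n_pl))]
  slots <- withr::with_seed(derive_seed(seed, "slots"), {
    free <- seq_len(n_slots)
    run_slots <- seq_along(planted_run)           # adjacent slots on chrom 1
    free <- setdiff(free, run_slots)
    rest_h <- sample(free, s$n_pairs - length(planted_run))
    free <- setdiff(free, rest_h)
    lnc_slots <- sample(free, n_lnc)
    list(run = run_slots, rest_h = rest_h, lnc = lnc_slots)
  })
  ids[slots$run] <- planted_run
  ids[slots$rest_h] <- setdiff(hg, planted_run)
  ids[slots$lnc] <- lnc_ids
  ann$gene_id <- ids
  lnc_bt <- rep(c("antisense", "lincRNA", "sense_intronic"), length.out = n_lnc)
  ann$biotype[match(lnc_ids, ann$gene_id)] <- lnc_bt

  # SNP catalog: one trait planted on DE genes, one on non-DE genes
  snps <- simulate_snp_catalog(
    ann, traits = c("trait_A", "trait_B"),
    planted = list(trait_A = hg[shared][seq_len(min(6, n_pl))],
                   trait_B = setdiff(hg, hg[shared])[seq_len(min(6, s$n_pairs - n_pl))]),
    snps_per_trait = 6, background_snps = 30,
    seed = derive_seed(seed, "snps"))

  # functional-class map over human genes
  terms <- withr::with_seed(derive_seed(seed, "terms"), list(
    class_planted = unique(c(hg[shared][seq_len(min(8, n_pl))],
                             sample(hg, 4))),
    class_random = sample(hg, 10)))

  # lncRNA expression: smooth profiles on a lower baseline; antisense
  # lncRNAs are planted as DE (the biotype-skew ground truth)
  lnc_sim <- simulate_ortholog_timecourse(
    n_pairs = n_lnc, frac_shared = 1, frac_shifted = 0,
    noise_sd = s$noise_sd, n_replicates = s$n_replicates, timepoints = tps,
    seed = derive_seed(seed, "lnc"), baseline = 2, amplitude = 1)
  lnc_tc <- lnc_sim$human
  rownames(lnc_tc$values) <- lnc_ids
  lnc_de_planted <- lnc_ids[lnc_bt == "antisense"]
  lnc_de <- simulate_de_tables(
    n_lnc, tps,
    list("24" = data.frame(gene = lnc_de_planted, direction = "up",
                           log2fc = seq(1.5, 3, length.out = length(lnc_de_planted)),
                           stringsAsFactors = FALSE)),
    seed = derive_seed(seed, "lnc_de"), genes = lnc_ids)

  inputs <- list(
    expression_human = write_expression_tsv(sim$human, file.path(dir, "expression_human.tsv")),
    expression_mouse = write_expression_tsv(sim$mouse, file.path(dir, "expression_mouse.tsv")),
    de_human = write_de_table(de_h, file.path(dir, "de_human.tsv")),
    de_mouse = write_de_table(de_m, file.path(dir, "de_mouse.tsv")),
    orthologs = write_ortholog_map(sim$orthologs, file.path(dir, "orthologs.tsv")),
    annotation = write_annotation_tsv(ann, file.path(dir, "annotation.tsv")),
    snps = write_snp_table(snps, file.path(dir, "snps.tsv")),
    terms = write_term_map(terms, file.path(dir, "terms.tsv")),
    lnc_expression = write_expression_tsv(lnc_tc, file.path(dir, "lnc_expression.tsv")),
    lnc_de = write_de_table(lnc_de, file.path(dir, "lnc_de.tsv")))
  tsv_out(sim$truth, dir, "sim_truth.tsv")
  inputs
}

#' Run the full comparative time-course pipeline
#'
#' Executes the enabled stages in order: simulate (generates every input with
#' planted ground truth) -> filter -> rank -> concord -> gp -> cluster ->
#' enrich -> coloc -> lncrna.  Each stage reads its inputs from files, writes
#' one or more TSVs under `out_dir`, and a JSON run manifest (config, seed,
#' package version, per-stage row counts, output file checksums) is written
#' at the end.  A stage failure halts the run with the stage name and cause.
#'
#' The stage names map one-to-one onto the module functions:
#' `simulate` = the `simulate_*` generators, `filter` = [filter_expressed()],
#' `rank` = [ranked_sets()], `concord` = [concordant_pairs()],
#' `gp` = [bayes_factor_table()], `cluster` = [cluster_profiles_kmeans()],
#' `enrich` = [link_snps_to_genes()] + [enrich_gene_sets_vs_traits()] +
#' [hypergeom_enrich()], `coloc` = [find_clusters()] +
#' [permutation_pvalues()], `lncrna` = the `lnc_*` / biotype / correlation
#' functions.
#'
#' @param config a `PipelineConfig` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return (invisibly) the manifest list; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir <- cfg$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- cfg$stages
  p <- cfg$params
  counts <- list()
  files <- character()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  inputs <- cfg$inputs
  if (isTRUE(st$simulate)) {
    inputs <- run_stage("simulate", simulate_stage(cfg, dir))
    counts$simulate <- length(inputs)
  }
  need <- function(key) {
    path <- inputs[[key]]
    if (is.null(path) || !file.exists(path))
      stop(sprintf("missing input '%s' (%s)", key, path %||% "no path configured"))
    path
  }

  tc_h <- NULL; tc_m <- NULL; kept_h <- NULL; kept_m <- NULL
  if (isTRUE(st$filter)) run_stage("filter", {
    tc_h <- read_expression_tsv(need("expression_human"), species = "human")
    tc_m <- read_expression_tsv(need("expression_mouse"), species = "mouse")
    kept_h <- filter_expressed(tc_h, p$rpkm_coding)
    kept_m <- filter_expressed(tc_m, p$rpkm_coding)
    files <- c(files,
                tsv_out(data.frame(gene_id = kept_h), dir, "filtered_human.tsv"),
                tsv_out(data.frame(gene_id = kept_m), dir, "filtered_mouse.tsv"))
    counts$filter <- c(human = length(kept_h), mouse = length(kept_m))
  })

  rs_h <- NULL; rs_m <- NULL; de_tab_h <- NULL; de_tab_m <- NULL
  if (isTRUE(st$rank)) run_stage("rank", {
    de_tab_h <- read_de_table(need("de_human"))
    de_tab_m <- read_de_table(need("de_mouse"))
    rs_h <- ranked_sets(de_tab_h, p$fdr, p$fc_floor, p$fraction)
    rs_m <- ranked_sets(de_tab_m, p$fdr, p$fc_floor, p$fraction)
    flat <- function(rs, species) do.call(rbind, lapply(names(rs$by_timepoint), function(tp)
      do.call(rbind, lapply(c("up", "down"), function(d) {
        g <- rs$by_timepoint[[tp]][[d]]
        if (!length(g)) return(NULL)
        data.frame(species = species, timepoint = tp, direction = d,
                   rank = seq_along(g), gene = g, stringsAsFactors = FALSE)
      }))))
    ranked <- rbind(flat(rs_h, "human"), flat(rs_m, "mouse"))
    files <- c(files, tsv_out(ranked, dir, "ranked_sets.tsv"))
    counts$rank <- nrow(ranked)
  })

  ortho <- NULL; conc <- NULL
  if (isTRUE(st$concord)) run_stage("concord", {
    ortho <- read_ortholog_map(need("orthologs"))
    conc <- concordant_pairs(rs_h, rs_m, ortho)
    files <- c(files, tsv_out(conc, dir, "concordant_pairs.tsv"))
    counts$concord <- nrow(conc)
  })

  if (isTRUE(st$gp)) run_stage("gp", {
    if (is.null(ortho)) ortho <- read_ortholog_map(need("orthologs"))
    pairs <- if (!is.null(conc) && nrow(conc))
      unique(conc[, c("human_gene", "mouse_gene")]) else ortho
    if (nrow(pairs) > p$gp_max_pairs)
      pairs <- pairs[seq_len(p$gp_max_pairs), , drop = FALSE]
    bft <- bayes_factor_table(tc_h, tc_m, pairs,
                              dt_grid = seq(-p$dt_max, p$dt_max, by = p$dt_step),
                              restarts = p$gp_restarts,
                              seed = derive_seed(cfg$seed, "gp"),
                              bf_threshold = p$bf_threshold)
    files <- c(files, tsv_out(bft, dir, "bayes_factors.tsv"))
    counts$gp <- nrow(bft)
  })

  if (isTRUE(st$cluster)) run_stage("cluster", {
    de_h_genes <- intersect(unique(call_de(de_tab_h, p$fdr, p$fc)$gene_id), kept_h)
    de_m_genes <- intersect(unique(call_de(de_tab_m, p$fdr, p$fc)$gene_id), kept_m)
    cl <- cluster_profiles_kmeans(tc_h, tc_m, de_h_genes, de_m_genes, ortho,
                                  k = min(p$k, length(de_h_genes) + length(de_m_genes) - 1),
                                  restarts = p$kmeans_restarts,
                                  seed = derive_seed(cfg$seed, "cluster"))
    files <- c(files,
                tsv_out(data.frame(gene = names(cl$assignments),
                                   cluster = unname(cl$assignments)),
                        dir, "cluster_assignments.tsv"),
                tsv_out(cl$pairs, dir, "coclustered_pairs.tsv"))
    counts$cluster <- nrow(cl$pairs)
  })

  ann <- NULL
  if (isTRUE(st$enrich)) run_stage("enrich", {
    ann <- read_annotation(need("annotation"), "tsv")
    snps <- read_snp_table(need("snps"))
    trait_map <- link_snps_to_genes(snps, ann, p$window, p$snp_p)
    common <- unique(conc$human_gene)
    sets <- list(common = common,
                 human_top20 = union(rs_h$merged$up, rs_h$merged$down),
                 mouse_top20 = union(rs_m$merged$up, rs_m$merged$down))
    human_universe <- intersect(ann$gene_id,
                                unique(c(de_tab_h$gene_id, ortho$human_gene)))
    universes <- list(common = ortho$human_gene,
                      human_top20 = human_universe,
                      mouse_top20 = ortho$mouse_gene)
    enr <- enrich_gene_sets_vs_traits(sets, trait_map, universes,
                                      ortho = ortho, mouse_sets = "mouse_top20")
    trait_tab <- do.call(rbind, lapply(names(enr), function(nm)
      if (nrow(enr[[nm]])) cbind(set = nm, enr[[nm]]) else NULL))
    files <- c(files, tsv_out(trait_tab, dir, "trait_enrichment.tsv"))
    terms <- read_term_map(need("terms"))
    fun_tab <- hypergeom_enrich(intersect(sets$human_top20, human_universe),
                                terms, human_universe)
    files <- c(files, tsv_out(fun_tab, dir, "functional_enrichment.tsv"))
    counts$enrich <- c(traits = nrow(trait_tab), classes = nrow(fun_tab))
  })

  if (isTRUE(st$coloc)) run_stage("coloc", {
    if (is.null(ann)) ann <- read_annotation(need("annotation"), "tsv")
    q <- intersect(unique(conc$human_gene), ann$gene_id)
    pv <- permutation_pvalues(q, ann, d = p$d, n_perm = p$n_perm,
                              seed = derive_seed(cfg$seed, "coloc"))
    obs <- pv$observed
    obs$p_global <- rep(pv$global$p, nrow(obs))
    files <- c(files, tsv_out(obs, dir, "colocalization_clusters.tsv"),
                tsv_out(pv$per_size, dir, "colocalization_per_size.tsv"))
    if (nrow(pv$observed))
      files <- c(files, write_cluster_tracks(pv$observed,
                                              file.path(dir, "colocalization_tracks.tsv")))
    counts$coloc <- nrow(pv$observed)
  })

  if (isTRUE(st$lncrna)) run_stage("lncrna", {
    if (is.null(ann)) ann <- read_annotation(need("annotation"), "tsv")
    lnc_tc <- read_expression_tsv(need("lnc_expression"), species = "human")
    lnc_de_tab <- read_de_table(need("lnc_de"))
    pre <- subset_timepoints(lnc_tc, lnc_tc$timepoints[1L])
    post <- subset_timepoints(lnc_tc, lnc_tc$timepoints[-1L])
    sets <- lnc_expression_sets(pre, post, p$rpkm_lnc)
    de_set <- de_lncrnas(lnc_de_tab, sets$expressed_after, p$fdr, p$fc)
    bio <- biotype_representation(de_set, sets$expressed_after, ann)
    nearest <- do.call(rbind, lapply(de_set, nearest_coding_gene, ann = ann))
    files <- c(files,
                tsv_out(data.frame(gene_id = sets$expressed_after), dir,
                        "lnc_expressed.tsv"),
                tsv_out(data.frame(gene_id = de_set), dir, "lnc_de.tsv"),
                tsv_out(bio, dir, "lnc_biotype_representation.tsv"))
    if (!is.null(nearest))
      files <- c(files, tsv_out(nearest, dir, "lnc_nearest_coding.tsv"))
    de_coding_h <- intersect(unique(call_de(de_tab_h, p$fdr, p$fc)$gene_id),
                             rownames(tc_h$values))
    if (length(de_set) && length(de_coding_h)) {
      corr <- top_correlated_coding(profile_matrix(lnc_tc, de_set),
                                    profile_matrix(tc_h, de_coding_h),
                                    top_n = 5)
      corr_tab <- do.call(rbind, lapply(names(corr), function(id)
        rbind(cbind(lnc = id, sign = "positive", corr[[id]]$positive),
              cbind(lnc = id, sign = "negative", corr[[id]]$negative))))
      files <- c(files, tsv_out(corr_tab, dir, "lnc_coding_correlation.tsv"))
    }
    counts$lncrna <- c(expressed = length(sets$expressed_after),
                        de = length(de_set))
  })

  manifest <- list(
    package = "orthokinetics",
    version = as.character(utils::packageVersion("orthokinetics")),
    seed = cfg$seed,
    config = unclass(cfg),
    stage_counts = counts,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
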