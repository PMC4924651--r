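# orthokinetics

Cross-species comparison of gene-expression time-course kinetics, built
around a Gaussian-process Bayes-factor test for conserved — possibly
time-shifted — ortholog expression.

## The problem

When the same cellular response is profiled in two species (the motivating
study: human and mouse CD4+ T cells polarized towards the Th17 lineage,
RNA-seq at 0, 0.5, 1, 2, 4, 6, 12, 24, 48 and 72 h with three replicates),
the question of which one-to-one orthologs respond with *conserved kinetics*
decides which genes can be studied faithfully in the mouse model.
Conservation has to tolerate a species-specific lag: a gene may follow the
same trajectory a few hours earlier or later.

`orthokinetics` answers this per ortholog pair by comparing two models of the
standardized log₂ expression profiles:

* **shared** — both species' replicate observations are draws from a single
  latent function f(t) under a Gaussian-process prior with the
  neural-network covariance k(x,x′) = σ_f² · asin( x̃ᵀΣx̃′ /
  √((1 + x̃ᵀΣx̃)(1 + x̃′ᵀΣx̃′)) ), x̃ = (1, x)ᵀ, Σ = diag(l⁻²), after adding a
  time shift Δt ∈ [−24, 24] h to the mouse time points;
* **independent** — each species gets its own GP.

Hyperparameters (length scale l, signal variance σ_f², noise variance σ_n²)
are set by MAP under Gamma priors (l ~ Γ(6,30), σ_f² ~ Γ(10,10), σ_n² ~
truncated Γ with its mode at the mean replicate variance); Δt is optimized on
a 2 h grid. The models are compared with the Bayes factor of plug-in marginal
likelihoods,

    BF = P(Y_mouse ∪ Y_human | θ̂_shared) / [ P(Y_mouse | θ̂_mouse) · P(Y_human | θ̂_human) ],

and **BF > 10** calls the pair *shared*. A positive Δt̂ means the mouse
profile leads the human one on the shared clock.

Around this core sit the other stages of a full comparative study, each an
exported function group:

| stage | what it does |
|---|---|
| `filter_expressed`, `lnc_expression_sets` | RPKM ≥ 3 (coding) / ≥ 0.5 (lncRNA) in ≥ 2 replicates at some time point |
| `call_de`, `rank_top20`, `ranked_sets` | FDR < 0.05, \|log₂FC\| > 1 DE calls; top-20% fold-change ranking per time point |
| `concordant_pairs`, `correlate_ortholog_expression` | cross-species concordance over merged time points; profile correlations |
| `cluster_profiles_kmeans`, `hierarchical_order` | joint k-means (k = 30) of both species' profiles; Ward ordering |
| `link_snps_to_genes`, `hypergeom_enrich`, `enrich_gene_sets_vs_traits` | disease lead-SNP ±100 kb windows; hypergeometric trait/class enrichment with BH FDR |
| `find_clusters`, `permutation_pvalues` | chromosomal co-localization (≤ 3 intervening genes) with genome-permutation p-values |
| `biotype_representation`, `nearest_coding_gene`, `top_correlated_coding` | lncRNA biotype skew, neighbor assignment, lncRNA–mRNA co-expression |
| `simulate_*` | every pipeline input with planted ground truth |
| `run_pipeline` | all stages end-to-end from one YAML/R config |

## Worked example

Simulate a six-pair study with known ground truth (three shared pairs, one
pair shifted −6 h, one +6 h, one divergent) and run the GP comparison:

```r
library(orthokinetics)

sim <- simulate_ortholog_timecourse(n_pairs = 6, frac_shared = 0.5,
                                    frac_shifted = 0.25, shift_set = c(-6, 6),
                                    noise_sd = 0.2, seed = 42)
bft <- bayes_factor_table(sim$human, sim$mouse, sim$orthologs, seed = 42)
cbind(bft[, c("pair_id", "log_bf", "dt_hat", "call")], truth = sim$truth$class)
```

```
        pair_id log_bf dt_hat      call     truth
1 HG0001/MG0001  11.87      0    shared    shared
2 HG0002/MG0002  14.83      0    shared    shared
3 HG0003/MG0003  11.05      0    shared    shared
4 HG0004/MG0004  10.85      0    shared   shifted
5 HG0005/MG0005   6.73      4    shared   shifted
6 HG0006/MG0006 -29.76    -16 different divergent
```

The three shared pairs are called shared with Δt̂ = 0 (log BF ≈ 11–15, i.e.
BF far above 10). Both shifted pairs are also called shared — conserved
kinetics up to a lag — with Δt̂ reported at the 2 h grid resolution; noise at
this sample size can pull the estimate a grid step or two from the planted
shift. The divergent pair is rejected decisively (log BF ≈ −30). The full
pipeline version of this analysis, including ranking, clustering, SNP
enrichment, co-localization and lncRNA stages on generated files, is

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "results_demo"))
```

which writes one TSV per stage plus `manifest.json` (config, seed, file
checksums; identical config + seed ⇒ byte-identical outputs).

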