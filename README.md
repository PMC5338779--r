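# channelscreen

`channelscreen` is a tidyverse-native R package for discovering
cancer-stem-cell-enriched ion channel genes from bulk RNA-seq and linking
them to glioblastoma molecular subtype, anatomic tumor region, and patient
survival. It was built for the study design in which ~20 glioblastoma
stem-like cell (GSC) isolates are compared against a handful of normal
neural stem cell / astrocyte control lines, but every stage is a plain
function over data frames and applies to any tumor-vs-control screen of a
candidate gene set.

The pipeline stages, each its own module of exported functions:

| Stage | Functions | Method |
|---|---|---|
| Normalization | `tmm_factors()`, `cpm()`, `average_replicates()`, `group_means()` | TMM scale factors (double-trimmed, inverse-variance-weighted mean of M values), counts-per-million, arithmetic replicate averaging |
| Differential screen | `log2fc_screen()`, `signal2noise_rank()`, `gsea_es()`, `gsea_permutation_p()`, `select_candidates()`, `family_enrichment()` | log2 fold change with explicit zero policies; Signal2Noise score `(μ_t − μ_c)/(σ_t + σ_c)` with SD floor; weighted running-sum enrichment score with permutation null; top-k + abundance filter; family summaries |
| Subtype | `compute_centroids()`, `classify_by_centroid()`, `consensus_call()`, `hierarchical_cluster()` | median centroids over a signature, Spearman-maximizing assignment, replicate consensus, UPGMA / complete-linkage clustering with newick export |
| Regional profiles | `aggregate_by_region()`, `edge_enrichment()`, `abundance_classes()`, `family_region_proportions()`, `cell_type_specificity()` | two-level means over the 7 anatomic compartments (LE, IT, CT, PZ, PAN, HBV, MVP), ≥2-fold edge rule, ≥5 / <1 FPKM abundance classes |
| Survival | `stratify_quantile()`, `stratify_median()`, `km_estimate()`, `logrank_test()`, `mann_whitney()`, `kruskal_wallis()`, `mutation_association()` | 0.10/0.90 quantile or median splits, Kaplan–Meier product-limit curves, log-rank (Mantel–Cox), exact/approximate Mann–Whitney, ≥3-mutant-sample rule |
| Synthetic data | `simulate_expression()`, `simulate_regional()`, `simulate_survival()`, `simulate_subtype_reference()` | negative-binomial counts with planted effects and recorded ground truth; regional, survival and subtype generators |
| Orchestration | `run_config()`, `run_pipeline()` | end-to-end run from a config (or YAML) with TSV outputs and a digest-bearing JSON manifest |

Results come back as tibbles or small S3 objects with `tidy()`, `glance()`
and `autoplot()` methods, so everything composes with dplyr and ggplot2.
File formats are the field's standards: TSV/CSV (or MatrixMarket) expression
tables, Broad-dialect GMT gene sets, plain survival tables, newick trees.

## Worked example

Simulate a screen with 5% of genes planted at a true 8-fold (log2 effect 3)
tumor enrichment, normalize, rank, and select candidates:

```r
library(channelscreen)

cfg <- screen_sim_config(n_genes = 500, fraction_planted = 0.05,
                         planted_log2_effect = 3, seed = 42)
sim <- simulate_expression(cfg)

factors <- tmm_factors(sim$expr)           # TMM scale factors, geometric mean 1
cpm_mat <- cpm(sim$expr, factors)          # counts -> CPM
ranked  <- signal2noise_rank(cpm_mat, sim$metadata)
tumor_means <- group_means(cpm_mat, sim$metadata, "tumor")

sel <- select_candidates(ranked, tumor_means, top_k = 25, cpm_min = 1)
glance(sel)
#> # A tibble: 1 × 4
#>   n_candidates top_k cpm_min n_dropped_cpm
#>          <int> <dbl>   <dbl>         <int>
#> 1           25    25       1             0

mean(sel$candidates$gene_id %in% sim$truth$planted_gene_ids)
#> [1] 1
```

All 25 candidates are planted genes. The planted set is maximally enriched
in the ranking, with a permutation p at the floor of 1000 permutations:

```r
res <- gsea_permutation_p(cpm_mat, sim$metadata, sim$truth$planted_gene_ids,
                          n_perm = 1000, seed = 42, set_name = "planted_channels")
res
#> # gsea_result 'planted_channels': ES = 1, NES = 1.876, p = 0.000999 (1000 gene_set permutations)
#> 25 set members in a list of 500; leading edge of 25
autoplot(res)   # running-sum walk
```

Expression-stratified survival: simulate times whose hazard rises with
expression (β = 1 per SD), split at the 0.10/0.90 quantiles, and compare
the extreme strata:

```r
expr_row <- setNames(rlnorm(200, log(10), 0.5), sprintf("pt%03d", 1:200))
surv <- simulate_survival(expr_row, beta = 1, censor_rate = 0.1, seed = 42)
strata <- stratify_quantile(surv$expression, 0.10, 0.90)
keep <- strata != "excluded"
logrank_test(surv[keep, ], strata[keep])[, 1:3]
#> # A tibble: 1 × 3
#>   statistic    df       p_value
#>       <dbl> <int>         <dbl>
#> 1      36.2     1 0.00000000180

glance(km_estimate(surv[strata == "high", ]))
#> # A tibble: 1 × 3
#>       n n_events median_survival
#>   <int>    <int>           <dbl>
#> 1    20       19            49.4
```

High expressors reach median survival at 49 days — far sooner than the
low stratum, exactly as the planted hazard dictates — and the log-rank test
resolves the difference decisively.

## Vignette

`vignettes/channelscreen-methods.Rmd` documents the statistical model of
every stage, the generators' assumptions and what they deliberately omit,
the numerical conventions (zero policies, tie-breaks, degenerate inputs),
and the verification strategy behind the test suite.
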