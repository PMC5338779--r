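---
title: "Methods: screening for stem-cell-enriched ion channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for stem-cell-enriched ion channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelscreen)
```

# The problem

Glioblastoma stem-like cells (GSCs) drive tumor formation, invasion and
treatment resistance, and ion channels are increasingly implicated in those
malignant phenotypes. `channelscreen` implements a multi-stage screen that
starts from bulk RNA-seq counts of tumor stem-cell isolates and control
neural lines and ends with a short list of tumor-enriched ion channel genes,
then asks whether those genes track molecular subtype, anatomic tumor
region, and patient survival. Every stage is a plain function over tibbles,
and a synthetic-data module generates inputs with known ground truth so the
whole pipeline can be exercised and verified without any external downloads.

# The screening model

## Normalization

Raw counts are scaled with trimmed-mean-of-M-values (TMM) factors. For
sample $j$ against a reference sample $r$, each gene contributes a log
ratio $M_g = \log_2\!\frac{x_{gj}/N_j}{x_{gr}/N_r}$ and an average log
abundance $A_g$; genes with a zero count in either sample are excluded for
that pair only. The $M_g$ are doubly trimmed (30% on each $M$ tail, 5% on
each $A$ tail) and averaged with inverse binomial-variance weights, and the
factor is $2$ to that mean. The reference is the sample whose
upper-quartile/library-size ratio is closest to the cross-sample mean of
that ratio, and factors are rescaled to geometric mean 1. The trim
fractions are the method's published defaults; they are exposed as
parameters (`trim_M`, `trim_A`) but there is no reason to move them.
Counts-per-million are then
$\mathrm{CPM}_{gj} = 10^6 \, x_{gj} / (N_j f_j)$, replicates of an isolate
are averaged arithmetically on the CPM scale (the screen models isolates,
not libraries), and group means are taken over isolate columns.

## Differential screen

Two complementary views of tumor-vs-control differences are computed:

* **Fold change** — $\log_2(\bar{x}_\text{tumor}/\bar{x}_\text{control})$
  with a $\pm 2$ threshold. Zero denominators are handled by an explicit
  policy: `exclude` removes the gene from the fold-change arithmetic and
  reports it (`excluded_zero_denominator`), `replace` substitutes 0.01 for
  zero means before the ratio. Both policies agree exactly whenever the
  denominator is positive.
* **Signal2Noise ranking** —
  $s_g = (\mu_t - \mu_c)/(\sigma_t + \sigma_c)$ over isolate-level columns,
  with each class SD floored at
  $\max(\sigma,\, 0.2\,|\mu|,\, 0.04)$. The floor is the conventional
  adjustment that keeps near-constant genes from generating huge scores;
  both constants are parameters. Ties are broken lexicographically by gene
  ID so reruns are byte-identical.

The ranked list feeds a weighted running-sum enrichment score: walking down
the list, a gene-set member increments the sum by
$|s_g|^p / \sum_{\text{hits}} |s_g|^p$ (default $p = 1$) and a non-member
decrements it by $1/(N - N_\text{hits})$; the enrichment score (ES) is the
signed extremum of the walk and the leading edge is the members at or
before it. Significance comes from a permutation null: either random
same-size gene sets on the fixed ranking (`gene_set`, the default) or
re-ranking under permuted class labels (`phenotype`). With 20 vs 5 isolates
phenotype permutation is feasible but the class imbalance makes its null
coarse, which is why `gene_set` is the default; both are implemented. The
p-value is the one-sided upper-tail fraction with +1 smoothing,
$(1 + \#\{ES^\ast \ge ES\})/(B+1)$ — defined on the single enrichment tail
so that it is uniform under the null, which the test suite verifies by a
Kolmogorov–Smirnov check. NES divides ES by the mean $|ES^\ast|$ of the
same-sign null values.

Candidates are the top 40 ranked genes (taken from the tumor-enriched end;
a flag switches to absolute-score selection) that also pass a mean tumor
CPM $\ge 1$ abundance filter; both drop stages are recorded in an audit
table. Family-level summaries average $\log_2$ fold changes over family
members that survived the zero-denominator exclusion, report the proportion
of members with fold change strictly above 2, and omit families with at
most one usable member.

## Subtype assignment

Molecular subtype centroids (Classical, Mesenchymal, Neural, Proneural) are
per-gene medians over the labelled reference samples, restricted to a
signature gene list (nominally 770 genes). A sample is assigned to the
centroid with the largest Spearman rank correlation (average-rank ties, the
standard convention). Rank correlation makes the call invariant to any
strictly monotone transform of the sample's expression, so CPM-vs-array
scale mismatches do not matter. Replicates are classified separately and
combined by majority, with ties broken by the higher mean correlation and,
as a last resort, a fixed subtype order with a warning. Correlation ties in
a single call are resolved the same way. Hierarchical clustering supports
the two recipes used alongside the classifier — euclidean/average (UPGMA)
and manhattan/complete — and emits newick via `ape`.

## Regional profiles

FPKM tables over the seven anatomic compartments (LE, IT, CT, PZ, PAN, HBV,
MVP) are aggregated by a two-level mean: replicates to sample, samples to
region. Per-sample values are retained so "majority of samples" statements
can be evaluated (operationalized as more than 50% of samples at or above
a threshold). Three per-gene rules follow:

* **edge enrichment** — mean(LE, IT) over the mean of all other region
  means, flagged at a $\ge 2$ ratio. A positive numerator over a zero
  denominator is infinite (flagged); $0/0$ is defined as 1 and never
  flagged, because absence of signal is not enrichment.
* **abundance classes** — `high` at $\ge 5$ FPKM in at least one region,
  `low` strictly below 1 FPKM in every region, `intermediate` otherwise;
  the three classes partition every gene.
* **family-by-region proportions** — fraction of family members strictly
  above 1 FPKM per region, shown only for families with at least three
  members.

Cell-type specificity uses a declared dominance convention: a gene is
`low_abundance` when no cell type reaches 1 FPKM; otherwise `specific` to
the top cell type when its mean is at least twice the runner-up, else
`multiple`. The factor of two is a package convention (the qualitative
source statements do not pin one down) and is a parameter.

## Survival

Cohorts are stratified by expression either at the 0.10/0.90 quantiles
(linear-interpolation quantiles, R's default type 7), with the middle 80%
excluded, or at the median, where values strictly above the median are
`high` — a value exactly at the median is `low`, consistent with "high"
meaning strictly above. Curves are Kaplan–Meier product-limit estimates
(via `survival::survfit`); the reported median is the first time the curve
reaches 0.5 or below. Two-stratum comparisons use the log-rank
(Mantel–Cox) test through `survival::survdiff`. Group comparisons of
expression use the Mann–Whitney test — exact when the smaller group has at
most 8 observations and the data are tie-free, otherwise the
tie-corrected normal approximation without continuity correction so that
the two-group case agrees with Kruskal–Wallis — and mutation associations
test mutant vs wildtype isolates per gene, skipping mutations carried by
fewer than three isolates. No multiplicity correction is applied across
genes; the number of tests is reported so users can correct post hoc.

# The synthetic-data generators

`simulate_expression()` draws negative-binomial counts — the standard
overdispersed model for RNA-seq — with lognormal per-gene baselines
(default $e^{N(\log 100,\ 1.5^2)}$ expected counts), a lognormal
isolate-level random effect (SD 0.1) shared by the replicates of an
isolate, uniform per-sample depth multipliers (0.7–1.3), and a planted
fraction of genes (default 5%) whose tumor mean is multiplied by
$2^{\text{effect}}$ (default effect 3). The defaults mirror the screen's
design: 20 tumor and 5 control isolates with 3 replicates each. The
isolate effect is what makes replicate averaging a meaningful stage; depth
variation is what makes TMM/CPM normalization a meaningful stage.

`simulate_regional()` draws lognormal noise around per-region mean FPKM;
`simulate_subtype_reference()` builds orthogonal block-shift centroids
(each subtype elevates its own block of signature genes above a common
baseline of 10, Gaussian noise floored at zero); `simulate_survival()`
draws exponential event times with hazard
$\lambda_0 e^{\beta z}$ for standardized expression $z$, with per-subject
Bernoulli censoring at a uniform fraction of the event time — a convention
chosen so `censor_rate` is exactly the expected censored fraction and
`censor_rate = 0` yields a fully observed cohort. All generators are pure
functions of their configuration including the seed.

What the generators deliberately do **not** model: batch effects beyond the
isolate random effect, gene–gene correlation, length bias in FPKM,
non-proportional hazards, and the mixed cell-type composition of real
regional samples. Green tests therefore demonstrate that the machinery is
correct under the stated generative assumptions, not that real data meet
those assumptions.

# Numerical choices and degenerate inputs

* TMM pairs where every gene is zero in one member fall back to factor 1
  with a warning, as do pairs where trimming removes every gene; a pair
  whose log-ratios are all below $10^{-6}$ in magnitude returns exactly 1.
* An all-zero sample column is an error for CPM (zero library size), not a
  silent NaN.
* Running-sum walks with all-zero hit scores at $p = 1$ fall back to equal
  hit increments.
* Spearman classification refuses constant sample vectors (undefined
  correlation) and requires at least 10 shared signature genes.
* Readers validate rather than repair: duplicate IDs, negative values and
  non-numeric cells are errors carrying file coordinates.
* All stochastic functions take a seed and restore the caller's RNG state
  (`withr::with_seed`), so library code never perturbs a user's session.

# Verification scale

The test suite checks every operation against an independent oracle —
a second step-by-step TMM implementation plus `edgeR::calcNormFactors`,
an explicit position-by-position running-sum loop, full enumeration for
exact Mann–Whitney p-values (all shapes with $n_1 + n_2 \le 12$), a
hand-coded product-limit estimator, a 20,000-draw permutation null for the
log-rank test, and brute-force median/Spearman/quantile evaluations. The
simulation-based checks run at deliberately chosen sizes: 50 seeds of a
1000-gene, 25-isolate screen for planted-gene recovery (median sensitivity
$\ge 0.9$, FDR $\le 0.1$); 200 replicates of 1000 permutations for null
p-value uniformity; 500 replicates for log-rank type-I error
($0.05 \pm 0.02$); 20 seeds over a 5-point noise grid for monotone subtype
degradation. These sizes balance statistical resolution against a test run
measured in tens of seconds; the properties they assert are
scale-invariant.

# Known limitations

* Only the Spearman-centroid subtype route is implemented; the external
  single-sample-predictor route can be plugged into `consensus_call()`,
  which consumes any per-replicate calls.
* The log-rank test is two-stratum only, matching its use here; no Cox
  regression or competing risks.
* Gene identifiers are opaque case-sensitive strings — no alias
  resolution. Gene-set members missing from a dataset are reported and
  treated as absent.
* FPKM is consumed as provided, never recomputed from counts.
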