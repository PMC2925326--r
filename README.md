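# coexmod

Co-expression modules and metabolic trait association for two-depot
adipose tissue transcriptomics.

## What it does

In paired subcutaneous (SAT) and visceral (VAT) adipose tissue
expression profiles, `coexmod` identifies **modules** of co-expressed
probes and relates their average expression to clinical traits. The
core algorithm is a greedy average-linkage agglomeration on Pearson
correlation: starting from individual probes, the most strongly
*positively* correlated pair of current items (probes or modules) is
merged, the merged item's profile is recomputed as the unweighted mean
of its member probes, and the process repeats until the strongest
remaining pair falls below a threshold, by default

> stop when max₍pairs₎ r < 0.65, merging positive correlations only.

Module profiles are then tested against traits with Spearman rank
correlation under Bonferroni control over (modules × traits) — with 67
modules and 14 traits at α = 0.05 the per-test threshold is
0.05 / 938 = 5.33 × 10⁻⁵ — and significant pairs are re-examined with a
partial (rank-residualized) Spearman correlation given confounders,
both forward (trait given confounders) and reverse (confounder given
trait), to distinguish driving traits from confounded ones.

Around the core, the package provides:

- per-tissue quantile normalization (reference = mean of order
  statistics, ties averaged) and single-pass per-sample QC,
- SAT-vs-VAT Wilcoxon Mann-Whitney differential expression with strict
  fold-change bins (> 1.5, > 10) and random stratified selection of
  qRT-PCR validation candidates,
- one-sided hypergeometric gene-set overlap tests (log-space tails;
  default universe 20,000 genes) and cross-tissue module overlap
  tables,
- co-expression network edge lists (r > 0.65) and module-ordered
  correlation heatmap matrices,
- a synthetic two-depot cohort generator with planted modules, trait
  couplings, confounders and tissue fold changes — the ground truth for
  the whole test suite,
- `run_pipeline()`, an end-to-end driver writing TSV outputs and a run
  manifest.

## Worked example

```r
library(coexmod)

design <- cohort_design(
  n_samples = 70, n_background_probes = 200,
  modules = list(
    module_spec(12, 0.9, trait_links = c(HDL_cholesterol = -0.8)),
    module_spec(8, 0.9)),
  noise_sd = 0.5)
cohort <- generate_cohort(design, seed = 42)

sat  <- quantile_normalize(cohort$sat)
mods <- build_modules(sat, r_stop = 0.65)
mods
#> module_set [SAT]: 202 final item(s) over 220 probes (18 merges, r_stop = 0.65)
#>   2 multi-probe module(s); largest: 12, 8

mods5 <- filter_modules_by_gene_count(mods, min_genes = 5)
assoc <- associate_modules(mods5, cohort$traits, alpha = 0.05)
subset(as.data.frame(assoc), significant)
#>   module_id           trait  n        rho            p significant
#> 8        M1 HDL_cholesterol 69 -0.6045127 3.788629e-08        TRUE
```

The two planted blocks come out as the only multi-probe modules (12 and
8 probes, exactly the planted memberships), and the planted inverse
HDL-cholesterol link on the 12-probe module is recovered at
rho = −0.60, p = 3.8 × 10⁻⁸ — far below even the study-scale Bonferroni
threshold of 5.33 × 10⁻⁵ (n = 69 because the trait table carries
missing values). The 18 merges exceed the 18 planted within-block merge
steps by zero: no background probe was absorbed.

Overlap statistics work directly from printed contingency inputs:

```r
fisher_overlap(sizes = list(n_a = 31, n_b = 103, k = 13), universe = 20000)
#> overlap: k = 13 of |A| = 31, |B| = 103 in N = 20000; one-sided p = 1.56e-22 (OR = 160)
```

i.e. 13 of 31 macrophage-specific genes inside a 103-gene module, in a
20,000-gene universe.

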