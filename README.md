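# colonyexpr

Per-gene classification of yeast colony RNA-seq expression by genotype and
colony age/region.

Structured ("ruffled") colony morphology in budding yeast depends jointly
on genotype and on where and when in the colony you look. Given a gene ×
library count matrix from a balanced factorial design — four genotypes
spanning the smooth-to-ruffled spectrum (*tec1*Δ, wild type, *sfl1*Δ,
*dig1*Δ) × three spatiotemporal conditions (whole colony at day 2, day-5
interior, day-5 periphery) × three replicates — `colonyexpr` answers, for
every gene, *how* it responds and *which* recurring pattern it follows.

The pipeline:

1. **Normalization** — TMM scaling factors (doubly trimmed, precision-
   weighted mean of M-values against a 75th-percentile reference) and
   prior-damped log2 CPM: `value(g,j) = log2((y + p_j)·10⁶ / (N_j + 2p_j))`
   with the scaled prior `p_j = 20·N_j/N̄`.
2. **Per-gene two-factor ANOVA** — an additive model
   `y ~ genotype + spatio` (type II per-term SS, F against the additive
   residual) and an interaction model `y ~ genotype * spatio` (interaction
   SS adjusted for both main effects, sum-to-zero contrasts), each also
   tested against the single-mean null; Holm correction applied separately
   to the five p-value families across genes.
3. **Permutation FDR** — the adjusted p < 0.01 cutoff is calibrated by
   re-running the full fit + Holm procedure under label permutations.
4. **Partition cascade** — variance ≥ 0.2 → interaction (adjusted p ≤ 0.01,
   r² ≥ 0.9; weaker interactions set aside) → additive responders
   (model-vs-null p < 0.01, r² ≥ 0.7, split per-term into spatio-only /
   genotype-only / both).
5. **Pattern classification** — factor-isolation normalization, complete-
   linkage clustering of standardized profiles (genotype clusters G1–G3
   labeled by monotonicity along the smooth→ruffled order; interaction
   clusters I1–I9), and assignment of spatiotemporal template classes
   C1–C8 (C1 = (2,0,0), C2 = (0,2,2), …) by maximal Pearson correlation.
6. **Overlap statistics** — cross-tabulation of cluster memberships with
   exact Fisher tests (hypergeometric 2×2; network-algorithm r×c with a
   seeded Monte-Carlo fallback).

A negative-binomial simulator (`generate_counts()`, `spike_templates()`)
produces matched factorial count data with truth tables, so every stage is
validated by parameter recovery.

## Worked example

```r
library(colonyexpr)

sim <- generate_counts(synth_config(seed = 7))       # 1,000 genes x 36 libraries
nf  <- tmm_factors(sim$counts)
e   <- log_cpm(sim$counts, nf, prior_count = 20)
fits <- fit_all(e, sim$design)
cls  <- partition(fits)
table(cls$status)
#>           low_variance            interaction              set_aside
#>                    805                     50                      0
#>          additive_both   additive_spatio_only additive_genotype_only
#>                     50                     45                     49
#>         nonsignificant
#>                      1
partition_recovery(cls, sim$truth)
#>                               class   n sensitivity false_positive_rate
#> both_additive         both_additive  50        1.00                  NA
#> genotype_additive genotype_additive  50        0.98                  NA
#> interaction             interaction  50        1.00                  NA
#> null                           null 800          NA                   0
#> spatio_additive     spatio_additive  50        0.90                  NA
```

Most planted effect genes are recovered into their true class and no null
gene is called significant. (Sensitivities fluctuate by a few genes from
seed to seed; the acceptance criterion averages five seeds.) The published
overlap analysis is a two-liner:

```r
t2 <- as.matrix(read.csv(system.file("extdata", "cluster_overlap_published.csv",
                                     package = "colonyexpr"), row.names = 1))
fisher_rxc(t2)$p_value
#> [1] 2.053738e-08
fisher_2x2(both_factor_table(616, 129, 103, 6575), tail = "one_greater")$p_value
#> [1] 4.730394e-84
```

The `analysis/` directory holds the study-scale workflow as numbered
drivers — `01_simulate.R` (6,600-gene synthetic dataset),
`02_fit_models.R` (normalization, ANOVA, 100-permutation FDR),
`03_partition_cluster.R` (cascade, G/C/I clusters, recovery scoring),
`04_overlap.R` (overlap tests) — writing their tables under
`results/synthetic/`.

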