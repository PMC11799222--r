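# neuroprs

Imaging-genetics analysis of polygenic risk and regional brain lobe volumes
in neonatal cohorts, as a tested, reusable R pipeline.

The scientific question it serves: do common genetic variants associated
with a neurodevelopmental condition, aggregated into a polygenic risk score
(PRS), relate to the volumes of cortical lobes measured at birth — before
any behavioural phenotype can appear? The intended users are statistical
geneticists and imaging researchers who have (i) cohort genotypes, (ii)
external GWAS summary statistics, (iii) a per-region volume table from a
neonatal segmentation pipeline, and (iv) standard gene/pathway annotation —
or who want to develop and validate such an analysis against synthetic data
with known ground truth before touching restricted cohort data.

## What it computes

For lobe volume $y_\ell$ and aggregate score $s$ (PRS-PC1), each of six
lobes (frontal, temporal, parietal, occipital, fronto-temporal,
parieto-occipital) is fit by ordinary least squares:

$$ z(y_\ell) = \beta_\ell\, z(s) + \gamma' (PC_{1..3},\, GA,\, PMA,\,
  sex,\, TBV) + \varepsilon $$

with Benjamini–Hochberg FDR over the six p-values. The score is built by
clumping + thresholding: greedy LD clumping (250 kb, $r^2$ 0.1), scoring at
ten GWAS p-value thresholds $P_T \in \{10^{-8}, 10^{-6}, 10^{-5}, 10^{-4},
10^{-3}, 0.01, 0.05, 0.1, 0.5, 1\}$, then the first principal component of
the ten standardized scores (PRS-PC1). Upstream: call-rate, MAF,
missingness and exact Hardy–Weinberg SNP/sample QC, method-of-moments IBD
relatedness ($\hat\pi \geq 0.1875$ resolved randomly), and ancestry PCA
with outlier exclusion. Downstream: three stability tests (split-half
resampling, top-vs-bottom 20% score extremes, per-threshold regressions)
and an exploratory SNP-ranked gene-set analysis (per-SNP scans on the two
composites, partition at p < 0.01, coordinate SNP→gene mapping,
hypergeometric overrepresentation with Bonferroni control over
pathways × gene lists, and an empirical specificity null that records the
top pathway across random SNP draws of matched size).

A synthetic-data module (`sim_config()`, `generate_study()`) generates
LD-block genotypes, discovery summary statistics with planted causal SNPs,
realistic neonatal covariates, region volumes carrying opposite-sign planted
effects on the fronto-temporal (+) and parieto-occipital (−) composites,
and gene/pathway annotation with a planted causal pathway — so every stage
is testable with known truth.

## Worked example

```r
library(neuroprs)

cfg <- pipeline_config(
  sim = sim_config(n_samples = 400, n_snps = 800, n_blocks = 50,
                   n_causal = 12, beta_ft = 0.2, beta_po = -0.2, seed = 7),
  n_split_reps = 200, n_null_runs = 200, seed = 7)
out <- run_pipeline(cfg)
out$results$primary
```

```
              lobe   beta     se        p    p_fdr significant
           frontal  0.144 0.0274 3.04e-07 3.04e-07        TRUE
          temporal  0.319 0.0190 1.48e-43 8.88e-43        TRUE
          parietal -0.172 0.0279 2.59e-09 3.11e-09        TRUE
         occipital -0.228 0.0242 2.37e-18 3.55e-18        TRUE
   fronto_temporal  0.204 0.0213 6.79e-19 1.36e-18        TRUE
 parieto_occipital -0.204 0.0204 3.49e-20 1.05e-19        TRUE
```

The planted composite effects (±0.2) are recovered on the standardized
scale (`fronto_temporal` 0.204, `parieto_occipital` −0.204); the individual
lobes inherit shares of the composite effect with the planted signs. After
QC and cohort filters 274 of 400 simulated infants remain; PRS-PC1 explains
99.8% of the threshold-score variance here because a large simulated
discovery GWAS makes all ten scores nearly proportional (small discovery
cohorts lower this sharply). The split-half consistency fractions are 1.0
for all six lobes at these effect sizes:

```r
out$results$stability$split_half$consistency
#  frontal temporal parietal occipital fronto_temporal parieto_occipital
#        1        1        1         1               1                 1
```

The exploratory enrichment stage at these settings ranks the planted
pathway first but does not pass all three criteria (overlap 3 < 4):
individually weak causal SNPs (standardized per-SNP effects ≈ 0.06) rarely
clear the per-SNP p < 0.01 scan at n ≈ 270 — the expected behaviour for an
exploratory method under a weak polygenic signal.

```r
head(out$results$enrichment$tables$both, 1)
#     pathway overlap  p_hyper  p_bonf specificity_freq passes
#  PW_PLANTED       3 0.000046 0.00704            0.085  FALSE
```

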