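---
title: "Polygenic scores and regional lobe volumes in neonates: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores and regional lobe volumes in neonates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroprs)
```

# What the pipeline does

`neuroprs` implements an imaging-genetics analysis for neonatal cohorts:
does common-variant polygenic risk, summarized as a single score, associate
with the volumes of cortical lobes measured at birth? The pipeline runs in
five stages.

1. **Genotype QC.** Samples with call rate below 95% are removed; pairs with
   identity-by-descent relatedness `pi_hat >= 0.1875` (halfway between
   second- and third-degree relatives) are resolved by randomly keeping one
   member; SNPs that are non-autosomal, have minor allele frequency below
   0.05, are missing in more than 1% of samples, or fail an exact
   Hardy-Weinberg test at p < 1e-5 are removed.
2. **Ancestry control.** Principal components of the standardized genotype
   matrix; samples may be assigned to reference-panel clusters by nearest
   centroid in the first two components, and outliers beyond 3 SD on any of
   the first three components are excluded. The first three components enter
   the regressions as covariates.
3. **Polygenic scoring.** Greedy LD clumping (250 kb, r² 0.1), then scores
   at ten GWAS p-value thresholds (1e-8 ... 1), then a PCA across the ten
   standardized scores whose first component (PRS-PC1) is the single
   exposure used downstream.
4. **Association.** Six covariate-adjusted linear regressions —
   `Volume ~ PRS-PC1 + PC1..3 + GA + PMA + sex + TBV` — for the frontal,
   temporal, parietal and occipital lobes and the fronto-temporal and
   parieto-occipital composites, with Benjamini-Hochberg adjustment over the
   six p-values; plus three stability checks (split-half resampling, top vs
   bottom 20% score extremes, per-threshold regressions).
5. **Enrichment.** A per-SNP scan against the two composites, partitioning
   of sub-0.01 SNPs into three subsets, coordinate-based SNP-to-gene
   mapping, hypergeometric overrepresentation with Bonferroni control over
   pathways x gene lists, and an empirical specificity null that records the
   top-enriched pathway across random SNP draws of matched size.

# The model

Let $y_{i\ell}$ be the volume of lobe $\ell$ for infant $i$ and $s_i$ the
aggregate polygenic score. The primary estimate per lobe is the coefficient
$\beta_\ell$ in

$$ z(y_{i\ell}) = \beta_\ell\, z(s_i) + \gamma_1 PC_{1i} + \gamma_2 PC_{2i}
 + \gamma_3 PC_{3i} + \gamma_4 GA_i + \gamma_5 PMA_i + \gamma_6 sex_i
 + \gamma_7 TBV_i + \varepsilon_{i\ell}, $$

where $z(\cdot)$ is the z-score. Standardizing the volume and the score —
but not the covariates — makes $\beta_\ell$ a standardized effect
comparable across lobes of very different size; covariates on their natural
scale change nothing about $\beta_\ell$ beyond what adjustment itself does.
Two-sided p-values use the t distribution with residual degrees of freedom,
and the six p-values are BH-adjusted as one family.

## PRS-PC1

Scores at the ten thresholds are nested sums and therefore strongly
positively correlated; their first principal component captures what they
share without committing to one threshold. Columns are standardized before
the PCA (correlation-matrix PCA), because raw score variances differ by
orders of magnitude across thresholds and would otherwise dominate the
component arbitrarily; a covariance-mode could be added but the correlation
convention is the stable default. The component's sign is chosen to make
the sum of its correlations with the threshold scores positive, so "higher
PRS-PC1" always reads as "higher risk burden". With genuinely nested,
informative scores every per-threshold correlation comes out non-negative
under this rule; with pure noise columns the sum is positive but individual
correlations can be negative — this is a property of the data, not of the
convention.

## Scoring conventions

Per threshold, a sample's score is the effect-size-weighted sum of
effect-allele dosages over clumped SNPs below the threshold, divided by
twice the number of non-missing scored SNPs (the mean per-allele effect).
Normalizing by the per-sample non-missing count keeps scores comparable
under missingness; a raw-sum mode is available (`normalize = FALSE`).
Missing dosages are imputed at twice the effect-allele frequency. Strand
ambiguous A/T and C/G SNPs are dropped during harmonization rather than
frequency-resolved: in a small cohort the yield is not worth the flip risk.
Scores are invariant to affine rescaling of the discovery effect sizes, so
whether the discovery GWAS reported log-odds or linear effects does not
change any downstream standardized result.

# Quality-control details

* **HWE test.** Exact, not chi-square: conditional on the observed allele
  counts the heterozygote count has a hypergeometric-type null
  distribution; the two-sided p sums the probabilities of all
  configurations no more probable than the observed one. Computed on the
  log scale and normalized, so it is stable for thousands of genotypes. All
  samples are treated as founders (no pedigree input).
* **Relatedness.** Method-of-moments IBD from identity-by-state counts with
  in-sample allele frequencies and small-sample factorial-moment
  corrections; negative component estimates are truncated at zero before
  `pi_hat = P(IBD=2) + P(IBD=1)/2`, and reported values are capped at 1.05
  (the moment estimator can overshoot slightly). For chains or triangles of
  related samples the filter repeatedly resolves the currently
  highest-pi_hat pair, dropping one member at random (seeded), and
  re-checks — deterministic given the seed.
* **Ancestry by rule, not by eye.** Visual cluster assignment and outlier
  exclusion are replaced by nearest-centroid assignment (first two
  components; ties to the lexicographically smallest label) and a 3-SD rule
  on the first three components. Both thresholds are arguments.
  Components used as covariates are recomputed after outlier exclusion.
* **LD pruning** (for PCA and relatedness): 50-SNP windows, step 5,
  r² 0.2 — community defaults, configurable. Missing dosages are
  mean-imputed inside the pruning and clumping r² computations only.
* **Sex-discrepancy check** is out of scope (no X-chromosome model); a
  genetic-sex column, if supplied, can be compared externally.

# The synthetic cohort generator

The generator exists because the cohort data the analysis is designed for
is access-restricted. It emulates the statistical structure the analysis
assumes, with known ground truth, so every stage can be tested end to end.

* **Genotypes.** Haplotypes follow a first-order Markov chain within LD
  blocks: transition probabilities are chosen so each SNP keeps its drawn
  allele frequency exactly and adjacent SNPs have haplotype correlation
  `ld_rho` (clamped where the frequency pair makes it infeasible). Blocks
  are independent and tiled across autosomes 1-22 (5 kb within-block
  spacing, 500 kb between blocks). Missing calls are independent at
  `missing_rate`; the default, 0.2%, reflects array-quality data — a
  missing rate at or above the QC missingness threshold would describe data
  that largely fails its own QC.
* **Summary statistics.** `n_causal` SNPs (one per block, so clumping
  cannot merge two causal loci) get standardized effects from
  N(0, h²/n_causal); every SNP's reported per-allele effect is the true
  effect plus noise with SE = 1/sqrt(N · 2f(1-f)), p from the normal tail.
  Causal SNPs are drawn at intermediate frequencies (MAF 0.1-0.45): the
  discovery GWAS has power there, and planted signal cannot be silently
  removed by the MAF filter at the QC boundary.
* **Phenotypes.** GA ~ N(40.16, 1.22²) truncated at 37 weeks; PMA = GA +
  U(0, 4); sex balanced; a latent total brain volume (mean 380,251 mm³,
  SD calibrated near 49,000 mm³) grows linearly in GA, PMA and sex. Each
  parcellation region is its share of the latent volume plus Gaussian noise
  (default 10% of the region mean — tight coupling of regions to overall
  brain size, as in real morphometry). The standardized genetic value is
  planted on the fronto-temporal and parieto-occipital composites with raw
  coefficients calibrated so that the downstream total-SD-standardized
  regression coefficient equals `beta_ft` / `beta_po` exactly; the
  coefficient is split evenly between the two lobes of each composite.
  With opposite-sign defaults (+0.2/-0.2) the genetic contributions to
  realized TBV cancel almost exactly, so conditioning on TBV does not leak
  the planted effect; for asymmetric choices a small residual leak is
  possible and documented here rather than hidden. A 5% radiology-score-5
  rate and 2% duplicate sessions exercise the cohort filters.
* **Annotation and pathways.** 20 kb genes, one centred on each causal SNP,
  the rest tiled with 15 kb gaps (so some SNPs are intergenic); the planted
  pathway holds exactly the causal-host genes plus a few random members;
  decoys are random subsets.

**What the generator does not emulate:** long-range LD and real recombination
maps, population admixture and assortment, genotyping batch effects,
non-Gaussian volume distributions, segmentation error that correlates
across regions, and overlapping gene annotations. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative assumptions, not robustness to every artifact of real cohort
data.

# Stability checks: what they do and do not show

* **Split-half.** The cohort is split at random (sizes ⌊n/2⌋, ⌈n/2⌉); the
  score-PCA and the six regressions are recomputed within each half, and a
  replicate is consistent for a lobe when both halves reproduce the sign of
  the full-sample coefficient — the strictest unambiguous reading of
  "reproduces the primary result", since p-value replication at half the
  sample would be a different (underpowered) claim. One subtlety matters
  when interpreting nulls: within a fixed cohort the two half-sample
  estimates are anti-correlated around the full-sample estimate, so a
  single null cohort yields consistency fractions near 0 or 1; only the
  expectation over cohorts is 0.5. The test suite therefore averages over
  fresh simulated cohorts for the null check. Ancestry components are held
  fixed across splits (the score PCA is recomputed per half); recomputing
  genotype PCs per half would change a covariate, not the exposure, and is
  left as a possible extension.
* **Extremes.** Per threshold, volumes are residualized on the covariates
  and the top vs bottom 20% (by rank; floor sizes; ties broken by sample
  order) are compared with a Welch t-test. Residualizing first keeps the
  comparison aligned with the covariate-adjusted primary model; a
  raw-volume mode exists for sensitivity.
* **Per-threshold grid.** The primary regression repeated with each of the
  ten standardized threshold scores; descriptive, no multiplicity
  adjustment. Thresholds with no qualifying SNPs yield constant columns and
  are excluded with a warning.

# Enrichment details

"Risk allele frequency" in the per-SNP scan model is implemented as the
per-individual effect-allele dosage — a per-SNP scalar frequency would be
constant across individuals and inestimable. The scan is computed by
residualizing phenotype and dosages on the covariates once
(Frisch-Waugh), which is algebraically the full multiple regression and
keeps 100,000-SNP scans tractable. Monomorphic SNPs are flagged with p = 1.

Partition at p < 0.01 (strict) gives three disjoint subsets; genes are
selected when they contain a SNP within start-stop (1-based, both ends
inclusive); overlapping annotations all count. The hypergeometric test uses
the declared background count; gene lists are restricted to the background
universe when the background gene set is known. A pathway is *enriched* when
its Bonferroni-adjusted p (over pathways x gene lists) is below 0.05 and it
shares at least 4 genes with the list; it is *specific* when it is the
single most-enriched pathway (smallest p, ties to the smallest pathway id)
in fewer than 5% of random SNP draws of matched size from the full clumped
panel. Recording exactly one top pathway per run follows the method as
stated; recording all significant pathways per run is a stricter variant
that could be exposed later. The specificity null samples from the full
clumped panel — the population the observed subsets were drawn from.

# Numerical and degenerate-input choices

* OLS via QR; rank deficiency is an error naming the collinear columns.
* Exact-fit data (zero residual variance) report beta exactly, t = 0 and
  p = 1 rather than 0/0.
* PCA sign conventions are deterministic (largest-magnitude loading
  positive for genotype PCs; positive correlation sum for the score PC).
* Score columns with zero qualifying SNPs are zero with a warning;
  constant columns are excluded from the score PCA and the per-threshold
  grid.
* p-values are floored at the smallest positive double so they stay in
  (0, 1].
* All randomness flows from per-stage seeds derived from one master seed,
  so toggling one stage never shifts another stage's stream; equal seeds
  give byte-identical outputs.

# Problem sizes used in tests

The default test suite and the acceptance script exercise the pipeline at
desk scale, chosen as the smallest sizes at which the statistical claims
are meaningful: cohorts of 220-600 samples, panels of 350-1,000 SNPs in
35-60 LD blocks (5,000 SNPs for the scan-calibration check), 200 parameter
recovery replicates, 500 null-calibration replicates, 200 resampling draws
where the method itself prescribes 1,000 (the estimate is a frequency;
quadrupling draws only narrows its Monte-Carlo error), and 50 end-to-end
enrichment replicates. The command-line surface is the R API plus
`run_pipeline()`; a study at real scale (hundreds of thousands of SNPs)
would want the same algorithms backed by packed genotype storage, which is
deliberately out of scope here.

# Known limitations

* The IBD moment estimator needs a few hundred informative SNPs per pair
  before `pi_hat` noise stays away from the 0.1875 cutoff; tiny panels will
  produce false relatedness removals (a power loss, not a bias).
* Nearest-centroid ancestry assignment assumes roughly isotropic,
  well-separated clusters in the first two components.
* The enrichment stage inherits every known bias of overrepresentation
  analysis — larger, better-annotated pathways are favoured; the
  specificity null mitigates but does not remove this.
* No mixed models, no longitudinal structure, no imputation, no X/Y
  chromosomes.
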