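---
title: "Methods: polygenic scoring and expression aggregates in diverse cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scoring and expression aggregates in diverse cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divprs)
```

## Scope and motivation

`divprs` implements a complete polygenic-score analysis for case/control
cohorts of mixed genetic ancestry, together with the transcriptomic
companion analysis that summarizes a sample's expression profile into a
single disorder-weighted score. Cohorts of this kind -- for example
postmortem brain collections genotyped for psychiatric phenotypes -- are
usually access-controlled, so the package pairs every analysis stage with
a synthetic-data generator whose truth is recorded. Every statistical
claim the test suite makes is therefore checked against known simulation
truth or an independent brute-force oracle, never against unavailable
data.

The pipeline stages are: PLINK1 genotype I/O, sequential genotype quality
control, kinship estimation and relative pruning, principal-component
ancestry assignment against a labelled reference panel,
summary-statistic harmonization, LD clumping, pruning-and-thresholding
(P+T) polygenic scores, incremental pseudo-R² prediction, and the
differential-expression-weighted aggregate score.

## Genotype representation

Genotypes are held as an `n_samples x n_variants` integer dosage matrix
counting copies of `allele_1` -- the A1 column of the .bim file -- with
`NA` for missing calls. Fixing the counted allele package-wide removes
all sign ambiguity downstream: harmonization re-expresses every external
effect estimate per copy of the target's `allele_1`, and scoring never
needs to re-check allele codings. Positions are 1-based throughout, the
.bim convention; no interval arithmetic is needed anywhere in the
pipeline. Imputation quality (r²) travels in a sidecar table keyed by
variant id because the .bim format has no such column.

## Sequential quality control

`apply_qc()` applies, in a fixed order: variant missingness > 5%, sample
missingness > 2%, heterozygosity deviation |F| > 0.2, variant
missingness > 2% (a routine re-filter after sample removal), exact
Hardy-Weinberg p < 1e-6, duplicated variants (same chromosome, position
and allele set; first kept), strand-ambiguous variants (A/T and C/G),
and -- when imputation quality is present -- r² ≤ 0.8. Two choices
deserve comment:

* **All comparisons are strict.** A variant at exactly 5% missingness or
  exactly r² = 0.8 sits on the wrong side of a strictly-greater rule and
  is retained or removed accordingly; the boundary semantics are pinned
  by tests.
* **Statistics are recomputed on the retained data before each step.**
  A sample failing missingness is removed before Hardy-Weinberg is
  evaluated, so one badly genotyped sample cannot push variants below
  the HWE threshold; a fixture in the suite demonstrates exactly this
  order sensitivity.

The heterozygosity filter uses the moment estimator
F = (O_hom − E_hom)/(m − E_hom) with expected homozygosity
Σ(1 − 2p(1−p)) at cohort allele frequencies; no small-sample frequency
correction is applied, keeping the estimator fully specified and
testable. The Hardy-Weinberg test is the exact conditional enumeration
test (plain p, not mid-p): at QC's extreme tail (1e-6) the chi-square
approximation is anticonservative at low minor-allele frequency, while
the exact test's null distribution is correct at any count.

## Kinship and relative pruning

Pairwise relatedness uses the KING-robust moment estimator over the
variants non-missing in both members:
kin = (N_both-het − 2·N_opposite-hom)/(N_het(i) + N_het(j)),
paired with a frequency-normalized zero-IBD statistic
k0 = N_opposite-hom / Σ 2p²(1−p)², the observed opposite-homozygote
count over its expectation for an unrelated pair. True values per class
are kin/k0 = 0.5/0 (MZ), 0.25/0 (parent-offspring), 0.25/0.25 (full
siblings), 0.125/0.5 (second degree), 0/1 (unrelated). Classification
applies the standard threshold cascade in order (MZ, parent-offspring,
full siblings, second degree; first match wins), and pruning removes
**both** members of every pair classified second-degree or closer,
closing over chains; a greedy keep-one-per-cluster alternative is
available behind a flag but is not the default. The estimator is not
ancestry-adjusted: within-population accuracy is what the recovery tests
certify (≥ 90% per class at 20,000 variants), and kinship in strongly
admixed samples is a known limitation.

LD pruning before kinship/PCA is a greedy left-to-right scan dropping
any variant whose squared dosage correlation with a retained variant
within 1e7 bp exceeds 0.1 (a correlation threshold of √0.1). Both the
window and threshold are configurable; clumping for scoring (below) is
a separate, p-value-aware operation.

## Ancestry assignment

Principal components are computed on standardized dosages -- mean
imputation of missing calls, centering, scaling by √(2p(1−p)) -- via
eigendecomposition of the sample-sample covariance. With a labelled
reference panel the decomposition runs on the combined matrix over the
variant intersection, giving both cohorts scores on common axes. Each
target sample is assigned to the nearest reference-group centroid by
standardized Euclidean distance over the first 4 PCs (pooled
within-group SDs), with a 6-SD assignment radius beyond which a sample
is `not-assigned`. Both constants are configurable defaults chosen to be
generous for well-separated continental groups while still rejecting
outliers; assignment quality is tested at Fst = 0.1, where recovery of
simulated population labels is exact. Ancestry-specific PCs -- the
covariates for all score regressions -- are then recomputed within each
assigned group with no reference panel.

## Polygenic scores

Harmonization matches summary-statistic rows to target variants by id,
falling back to chromosome+position, and resolves allele order and
strand: direct match, sign-flip (effect allele is the target's
allele_2), strand-flip (complement both alleles), or both; ambiguous
A/T and C/G rows are dropped before any matching because their strand
cannot be inferred, and irreconcilable allele sets are dropped and
counted. Clumping is greedy and p-value-aware: the best remaining
variant becomes an index and removes unselected variants within 500 kb
at r² > 0.1; both parameters are configurable defaults in line with
common P+T practice. Scores at each threshold p_T sum aligned effect
times dosage over clumped variants with p < p_T -- strictly, except the
all-variant column p_T = 1.0 which is inclusive -- with missing dosages
replaced by twice the allele frequency (unbiased under
missing-at-random). The default grid of 13 thresholds spans 5e-8 to
1.0 with 0.05 as the conventional headline threshold.

## Prediction and variance explained

Binary phenotypes are analysed by maximum-likelihood logistic
regression; variance explained is the **incremental Nagelkerke
pseudo-R²** -- the full model (score + 10 ancestry-specific PCs) minus
the covariates-only model, with
R²_N = (1 − exp(−2(LL_model − LL_int)/n)) / (1 − exp(2·LL_int/n))
anchored at the intercept-only likelihood. This is the convention of the
psychiatric polygenic-score literature; a liability-scale transformation
is deliberately not the default. The score term's p-value is the Wald
test; perfect separation is detected and flagged rather than silently
reported. Quantitative phenotypes use ordinary least squares and the
incremental R². The 2x2 ancestry-by-diagnosis composition test uses the
Yates continuity-corrected chi-square (the correction term floors at
zero), with row proportions reported in percent to one decimal using
standard round-half-even arithmetic.

## Expression aggregate

Counts are transformed to logCPM = log2((count+0.5)/(libsize+1)·1e6).
Precision weights follow the voom recipe: per-gene unweighted fits,
a lowess trend (span 0.5) of √(residual SD) against average log2 count,
per-observation predicted SD read off the trend at the observation's
fitted log2 count, weight = SD⁻⁴. With fewer than 50 genes the trend is
unreliable and unit weights are substituted with a warning. Covariates
(library batch, sex, age, mapping rates, RIN, PMI, pH) are regressed
out per gene by weighted least squares; a data-driven
`select_covariates()` is provided (association of candidates with the
top 20 expression PCs at level 0.05, collinear candidates tied to the
same PC resolved at |r| > 0.6), but the fixed 8-covariate design is the
default so the pipeline runs without the selection step. Per-gene
case/control coefficients on the residuals (cases coded 1, so positive
means higher in cases) define the weights; the aggregate score of a
sample is the sum over nominally significant genes (two-sided p < 0.05,
unadjusted) of residual × coefficient, with no normalization.

Because the weights are learned **in-sample**, the case-minus-control
mean of the aggregate score equals the sum of squared flagged
coefficients and is nonnegative by construction. This optimism is a
property of the method being implemented, not an accident: the score is
meant as an in-cohort summary of case-like expression deviation, and
any out-of-cohort use would require refitting or cross-validation. The
test suite asserts the identity algebraically, and separately verifies
that weights learned on permuted labels produce no separation of the
true groups. Correlation with polygenic scores residualizes the genetic
score on the 10 ancestry-specific PCs first, then reports the Pearson
correlation with its t-test p-value.

## The synthetic-data generators

The generators define the study conditions used throughout the tests:

* **Genotypes**: Balding-Nichols population structure. Ancestral
  frequencies uniform on [0.05, 0.5]; two populations at Fst = 0.1 by
  default (realized Hudson-estimator Fst is verified to land in
  [0.07, 0.13]); genotypes binomial and independent across variants.
  Simulated variants carry non-ambiguous allele pairs; ambiguous and
  duplicate variants are planted explicitly by QC fixtures.
* **Phenotypes**: liability-threshold model. Liability is the
  empirically standardized genetic score over causal variants scaled to
  variance h² (default 0.5) plus independent Gaussian noise; cases
  exceed the quantile threshold of the default prevalence 0.3 --
  deliberately high, matching case-enriched collection cohorts rather
  than population prevalence. The liability itself doubles as the
  quantitative trait.
* **Summary statistics**: drawn analytically as Normal(true effect,
  se²) with se = 1/√(2p(1−p)·n_train) at training-population
  frequencies (population 1 plays the training ancestry), rather than
  by simulating a genotype-level training cohort -- orders of magnitude
  faster with the same downstream sampling behaviour. A configurable
  20% of rows has its allele representation scrambled (order swap
  and/or strand complement) so harmonization is exercised against
  recorded truth.
* **Relatives**: founders are drawn as phased haplotypes and offspring
  receive one haplotype per parent by independent per-locus
  transmission; MZ twins duplicate a genotype, second-degree pairs are
  grandparent-grandchild. Transmission indicators are kept, so each
  pair records its realized (not just expected) IBD kinship.
* **Expression**: negative-binomial counts around
  library-size-scaled means whose log2 scale combines a Gaussian
  baseline, per-gene covariate effects, and planted case/control
  log2-fold-changes on 10% of genes (SD 0.5); library sizes are
  log-normal. Dispersion 0.1 is typical of bulk RNA-seq after technical
  replication.

What the generators do **not** emulate: linkage disequilibrium beyond
explicitly constructed correlated blocks (clumping correctness is
certified on such blocks, not on haplotype models), sex chromosomes,
genotyping batch effects, and ancestry-correlated expression structure.
Passing tests therefore certify the machinery and its statistical
calibration, not performance on any particular real cohort.

## Problem sizes and numerical choices

The test suite uses deliberately modest problem sizes chosen so the
statistical assertions are well-powered: kinship recovery uses 20,000
variants and 50 replicates per relationship class; null calibration of
the incremental pseudo-R² uses 100 replicates of a 500-sample,
500-variant cohort (the pseudo-R² of a null 1-df term has positive
bias of roughly 1/(n·(1 − exp(2·LL₀/n))) ≈ 0.003 at n = 500, which the
centering band accounts for); signal recovery uses 10,000 variants,
1,000 causal, 2,000 target samples and an analytic training GWAS of
50,000. PCA for the ancestry adjustment in large simulations runs on a
random 2,000-variant subset, standard practice since the leading axes
are global. Score-machinery equivalence to the brute-force masked
matrix product is asserted to 1e-12; PCA orthogonality and
standardization identities to 1e-8 or better.

Degenerate inputs are handled explicitly rather than by convention:
monomorphic variants return Hardy-Weinberg p = 1 and are ineligible for
LD pruning (their correlation is undefined); samples whose non-missing
variants are all monomorphic get F = 0 with a warning flag; pairs with
no heterozygotes have undefined kinship and classify as unrelated with
a flag; thresholds passed no variants yield zero score columns with a
warning; zero flagged genes yield zero aggregate scores with a warning.

## Known limitations

* The kinship estimator is not ancestry-adjusted; cross-population or
  admixed pairs can be misclassified.
* P+T scoring is the classic approach; no LD-reference shrinkage
  methods are provided, and with independent simulated variants the
  clumping stage is exercised mainly by constructed correlated blocks.
* The aggregate expression score is in-sample by design (see above).
* The covariate-selection procedure is a reasonable default, not a
  reconstruction of any particular cohort's choices; the fixed
  8-covariate design is the supported default path.
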