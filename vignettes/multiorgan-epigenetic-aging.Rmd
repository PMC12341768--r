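---
title: "Multi-organ epigenetic aging from RRBS methylation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-organ epigenetic aging from RRBS methylation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratclocks)
```

## Scope and model

`ratclocks` implements a complete analysis chain for studying epigenetic
aging across multiple organs from reduced representation bisulfite
sequencing (RRBS) data: assembly and coverage-filtering of CpG
methylation matrices, four styles of elastic-net epigenetic clock,
per-sample global methylation statistics, promoter-level differential
methylation between two groups, and paired multi-organ comparisons of
epigenetic age acceleration. The motivating application is a two-line
rat model of intrinsic cardiorespiratory fitness (low- versus
high-capacity runners, LCR/HCR), with clocks trained on a public blood
RRBS cohort and applied to hippocampus, heart, soleus muscle, and large
intestine.

The central substrate is a samples x CpG-sites matrix of methylation
fractions $m \in [0,1]$ with explicit missingness (`NA`), paired with an
aligned integer read-coverage matrix. Fractions are used internally
everywhere; percentages appear only at I/O boundaries (Bismark `.cov`
and CGmap files, rDNA feature tables), because the entropy statistic
requires probabilities.

## Coverage rules

Two rules govern data quality, both with the read-depth bound
*inclusive* (a site with exactly 5 reads is kept):

* `mask_low_coverage()` sets individual values with fewer than
  `min_depth = 5` reads to missing;
* `filter_by_coverage()` keeps the sites covered by at least
  `min_depth` reads in at least `min_sample_fraction = 0.9` of samples.

Descriptions of this rule in the literature oscillate between a strict
and a non-strict inequality; the package fixes the inclusive reading and
makes `min_depth` configurable so the other convention is one argument
away. CpG sites are keyed by `"chrom:pos"` exactly as reported by the
source files; opposite-strand cytosines are never merged, since no
merging rule is defined for the source data.

## Elastic-net clocks

`train_elastic_net_clock()` fits `age ~ methylation` with a glmnet
elastic net at mixing parameter 0.5. Missing values are filled with
per-site means of the whole matrix before an 80/20 train/test split
(this ordering follows the original training protocol for the
blood-derived clocks; the rDNA model grid below deliberately uses the
stricter train-only order instead). The test-set size is
`round(0.2 * n)`, which reproduces the 107/27 split of a 134-sample
cohort. The penalty strength is chosen by 10-fold cross-validation on a
log-spaced path (`lambda.min` by default; `lambda.1se` or a fixed
numeric penalty are available), features are standardized internally
during fitting, and coefficients are returned on the original scale, in
months per methylation fraction. Only nonzero-weight sites are stored,
so a prediction is the affine form
$\hat a = b_0 + \sum_j w_j m_j$ over the clock sites.

**Age acceleration** is the residual from the *reference regression*: a
least-squares line of predicted on chronological age fitted on the
held-out test set. Acceleration is `predicted - (slope * age +
intercept)`; over the fitting set these residuals sum to zero.

**Applying a clock to sparse data.** RRBS coverage is random, so an
application profile may miss clock sites. `impute_clock_sites()` uses a
two-stage rule: a missing value is filled with the cohort mean of that
clock site over the samples that cover it, and a site covered in no
sample is filled with the mean of the sample's covered clock-site
values. The phrase "mean methylation values of the covered clock CpG
sites" is ambiguous between these two orientations; the package applies
the per-site mean first because it preserves between-site structure, and
falls back to the per-sample mean only when a site is entirely absent.

**Intersection clock.** For each test sample,
`intersection_predict()` restricts the training matrix to the CpGs the
sample actually covers, partitions the training samples into five
seed-deterministic folds, fits one elastic net per fold on the other
four folds (penalty selected by nested CV inside that fold's training
portion, avoiding leakage into fold predictions), and predicts with the
arithmetic mean of the five fold predictions (MeanPred). A 64-sample
cohort therefore entails 5 x 64 fitted models. The fold partition is
fixed once per cohort run: resampling folds per sample is not ruled out
by the method's description, but a fixed partition makes cohort runs
reproducible and lets samples with identical coverage patterns share
fitted models (the cache is exact: cached and uncached runs agree bit
for bit).

**rDNA clock.** The multi-copy ribosomal DNA repeat yields deep
coverage, so an rDNA-restricted feature table (percent scale, positions
on a single reference) is nearly complete and applies well to external
data. `run_model_grid()` evaluates four imputation techniques (mean,
KNN, SoftImpute, PCA) crossed with three model families (elastic net,
gradient boosting, random forest) on an 80/20 split, and
`select_best()` picks the minimum-MAE row (ties: higher Pearson r, then
fixed grid order). Hyperparameters are fixed, documented defaults --
boosting: 100 rounds, depth 3, learning rate 0.1; forest: 100 trees,
unlimited depth -- because none are specified for the original grid.
Imputation statistics are fitted on training rows only and test rows are
completed from training-side information (column means, training-row
neighbours, or least-squares projection onto the training SVD basis);
the original order of operations is ambiguous on this point and the
leakage-free order is the defensible default.

Imputation details: KNN distance is the root mean squared difference
over mutually observed features (scale-free in the feature count), with
a logged fallback to the column mean when no neighbour observes a cell.
SoftImpute iterates SVD reconstruction with soft-thresholded singular
values (threshold `lambda`, default 0, rank-capped) until the relative
change drops below `tol = 1e-4` (cap 200 iterations); its objective --
observed squared error plus the nuclear-norm surrogate -- is
non-increasing across iterations. PCA imputation is the column-centred
variant. All imputed values are clipped to the valid percent range, and
observed entries are never altered by any method.

## Global methylation statistics

For each sample, `sample_gmm()` is the mean methylation fraction over
observed sites and `sample_mme()` the mean of the per-site binary
Shannon entropy in bits,
$H(m) = -m\log_2 m - (1-m)\log_2(1-m)$, with $0\log_2 0 = 0$.
Both are computed over each sample's own observed sites (with
`n_sites_used` reported for auditability) rather than over a common
complete subset, which matches how the statistics are defined for
per-sample coverage-variable RRBS data. Group comparisons use a
two-sided Welch t-test: the original analyses do not name the two-group
test, and Welch is the robust default at n = 8 versus 8; the test suite
cross-checks its significance calls against a permutation oracle.
Significance stars follow the convention `ns` (p > 0.05), `*`
(0.01 < p <= 0.05), `**` (0.001 < p <= 0.01), `***` (p <= 0.001),
`****` (p <= 1e-4).

## Promoter analysis

The promoter of a gene is the closed interval [-1500, +500] bp around
the TSS following the direction of transcription (so on the minus
strand the window is [tss-500, tss+1500]), clipped at position 1; both
bounds are inclusive, giving a 2001-bp window. The TSS is taken from
the GTF *gene* feature (start on `+`, end on `-`); multi-transcript
resolution is out of scope. Per gene and sample, the promoter
methylation is the mean over the window's observed CpGs.

Differential testing between groups uses the same Welch test per gene,
with Bonferroni correction over G = the number of genes actually
testable in that organ (at least two non-missing promoter means per
group) -- G is the tested universe, not the full annotation.
`best_hits()` ranks by uncorrected p (lexicographic gene-id
tie-break); `common_significant_genes()` returns the genes with
uncorrected p strictly below alpha in *every* organ, reporting per-organ
directions without requiring them to agree (direction consistency is a
finding, not a filter). Benjamini-Hochberg adjustment is provided as a
generic utility via `stats::p.adjust`.

## The synthetic cohort generator

Because the real training accession and organ RRBS data are not
redistributable, every stage is exercised on simulated cohorts with
recorded ground truth. The generative model per site and sample is:

1. baseline methylation drawn from Beta(5, 2) -- a globally
   hypermethylated methylome, so that entropy drift toward 0.5 lowers
   global mean methylation as it raises entropy;
2. a minority of sites (default 4%) drift linearly with age, slopes
   from N(0, 0.01) fraction/month;
3. optional entropy drift: |m - 0.5| shrinks proportionally to
   age/age_max with strength `entropy_drift`, which produces a positive
   MME-age and negative GMM-age correlation by construction;
4. Gaussian biological noise (sd 0.05), then clamping to [0, 1];
5. read coverage from a negative binomial (mean 30, dispersion 5;
   overdispersion mimics RRBS site-coverage variability), with a
   configurable fraction of entries forced below the 5-read mask
   threshold, and methylated reads Binomial(coverage, m) -- observed
   fractions are always exactly methylated/total reads.

Defaults depict a lifespan-wide blood training cohort: 134 samples aged
uniformly over 1-27 months (the real training set's age distribution is
not published, so a uniform lifespan-wide draw is assumed and stated,
not inferred). The multi-organ generator crosses 2 groups x 8
individuals x 4 organs = 64 samples, places a fixed number of CpGs in
each annotated promoter window, and supports per-(organ, gene) group
effects (added to the effect group's promoter CpGs), per-organ global
methylation offsets, and per-organ age-acceleration offsets. Passing
the training cohort as `template` reuses its site coordinates,
baselines and age slopes for background sites, emulating that training
and application data come from the same genome -- the property that
makes blood-trained clocks transferable at all.

What the simulator does *not* emulate: bimodal CpG-island structure,
spatial correlation along the genome, strand effects, bisulfite
conversion error, sex effects, and realistic inter-organ covariance
beyond the injected offsets. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under a known
generative model, not biological validity on real RRBS data.

## Numerical and design choices

* Split sizes: test = `round((1-f) n)`; verified against the 107/27
  reference split.
* The closed-form "noise floor" used to judge clock recovery is the
  Fisher-information bound for the generative model,
  $\sqrt{2/\pi}\,\sigma_{obs}/\sqrt{\sum_j s_j^2}$ with
  $\sigma_{obs}^2 = \sigma_{noise}^2 + E[m(1-m)]/\bar c$; the trained
  clock is required to come within a factor 2 of it.
* Degenerate inputs: constant ages refuse to train; constant vectors
  refuse a Pearson r; paired organ tests with zero-variance differences
  are flagged degenerate instead of receiving an arbitrary p; zero
  coverage yields a missing fraction, never 0/0.
* Exactly identical groups in a Welch comparison report statistic 0 and
  p = 1.
* Multiple testing across the six organ pairs of the paired comparisons
  is reported raw with stars (mirroring the presentation convention for
  such figures) plus an additional BH-adjusted column.
* Problem sizes in the test suite (e.g. 5,000-site training cohorts,
  1,250-site null cohorts, 50-seed recovery loops) are chosen to give
  stable statistical behaviour at interactive runtimes.

## Limitations

The package does not perform read processing, bisulfite alignment,
methylation calling, or genome-build liftover; it consumes already
called per-CpG tables. It does not attempt to reproduce the exact
published clock site sets or real-data error statistics, which depend on
the non-bundled training accession. Functional enrichment of gene lists
is out of scope beyond exporting them.
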