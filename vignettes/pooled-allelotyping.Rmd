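---
title: "Pooled-DNA allelotyping on SNP arrays: models, QC and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-DNA allelotyping on SNP arrays: models, QC and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelopool)
library(dplyr)
```

# The estimation problem

Genotyping every individual of a population sample on a SNP array is
expensive; pooling equal amounts of DNA from all individuals and assaying
the pool once gives, per locus, a single allelic intensity ratio
θ ∈ [0, 1] whose expectation moves continuously with the pool's B-allele
frequency. `allelopool` implements the interpolation estimator that turns a
pool θ into a frequency, together with everything a careful study needs
around it: a genotype-calling surrogate to build the reference clusters, a
locus QC cascade tuned to degraded-DNA data, replicate repeatability
metrics, and a resampling framework that answers the design question "how
many individually genotyped reference samples do I need?".

# The estimator

With per-locus reference cluster means θ̄~AA~ < θ̄~AB~ < θ̄~BB~, the pool
frequency is

* 0 for θ at or below θ̄~AA~, 1 for θ at or above θ̄~BB~;
* 0.5 · (θ − θ̄~AA~)/(θ̄~AB~ − θ̄~AA~) between the AA and AB means;
* 0.5 + 0.5 · (θ − θ̄~AB~)/(θ̄~BB~ − θ̄~AB~) between the AB and BB means.

Two conventions are deliberate:

* **Boundaries by continuity.** Written as strict inequalities the two
  interior branches leave θ exactly equal to θ̄~AB~ unassigned; both branch
  formulas agree there (value 0.5), so `estimate_freq()` returns 0.5 and is
  continuous and non-decreasing on all of [0, 1]. This is asserted to
  1e-12 on a 201-point grid in the tests.
* **Required-cluster rule.** All three cluster means must be defined for
  *any* estimate, even when θ falls in a saturation branch. A reference
  panel that never sampled a BB individual cannot place θ̄~BB~, and a θ in
  the AA tail gives no evidence about where saturation begins. The
  estimate is then an explicit *inestimable* state (`NA` plus a `reason`),
  not an exception — small reference panels are expected to produce these,
  and the resampling analysis counts them. A laxer rule would inflate
  apparent coverage; it is not offered as a default.

The estimator uses θ only; the total intensity R is carried through the
file formats for completeness but never consulted.

# The genotype-calling surrogate

Commercial array-clustering software is proprietary, so reference clusters
are fitted here as ordered univariate Gaussian mixtures on θ
(`mclust`, 1–3 components, equal- or unequal-variance models, BIC
selection). Fitted components are labelled AA/AB/BB by an order-preserving
assignment that minimises total distance to anchor positions — by default
(0.05, 0.50, 0.95) for diploid SNPs and (0.05, 0.275, 0.50) for MSV-3 loci,
whose usable θ span is roughly halved because the polymorphism sits on one
paralogue of a duplicated region.

Numerical choices worth knowing:

* **Minimum cluster occupancy 2** for a class mean to be considered
  defined: a one-point "cluster" has no dispersion estimate.
* **Degenerate inputs** (fewer than two observations, or at most three
  distinct θ values) bypass the mixture fit: distinct values become
  clusters directly, which also makes the zero-noise synthetic path exact.
* **Per-locus quality** is summarised by a GenTrain-like separation score
  `1 − exp(−sep/4)` where `sep` is the minimum adjacent
  |Δmean|/pooled-sd; a locus with fewer than two defined clusters gets a
  configurable degeneracy value (default 0).
* **Per-call confidence** is GenCall-like:
  `exp(−z₁²/2) · z₂/(z₁ + z₂)`, with z₁ the standardised distance to the
  assigned cluster and z₂ to the nearest competitor; it is 1 at a cluster
  centre and decreases monotonically with distance. Cluster standard
  deviations are floored at 1e-6 so zero-dispersion clusters still score.
  Exact score ties are broken toward the lower-θ genotype, for
  determinism. Calls below the threshold (profiles: 0.15 for the small
  stringent design, 0.05 for the large pooling design) become `NOCALL`.
* **Visual cluster inspection** is replaced by rule-based review flags
  (`cluster_flags()`): adjacent-cluster separation below 2 pooled
  standard deviations, or an unclusterable locus. Absent classes are
  recorded but do not flag a locus by themselves — a monomorphic locus
  legitimately shows one cluster.
* Samples excluded by the raw call-rate screen are simply not fed to the
  cluster fit; if calls are still wanted for them they can be called
  against the fitted models afterwards, and should be treated as flagged.

# The QC cascade

Locus filters are independent predicates, so their order does not affect
the final pass set:

1. **Classification**: only SNP, MSV-3 and monomorphic classes are
   analysable; UNKNOWN/MSV-5/PSV/MITO/FAILED are discarded.
2. **Locus call rate** ≥ 0.95 over QC-retained samples (strictly below
   fails, exactly at the threshold passes).
3. **Heterozygote excess/deficit**: |het~obs~ − 2p(1−p)| ≤ 0.1, with p the
   B-allele frequency from genotype counts. This is read as a frequency
   difference (the most direct reading; an inbreeding-coefficient reading
   would rescale with MAF), and the threshold is configurable — small
   reference panels conventionally relax it to 0.5 because the statistic
   inflates at small n. In duplicated genomes this filter catches loci
   polymorphic on both paralogues masquerading as single SNPs.
4. **Polymorphism screen**: MAF strictly above 0.05, computed by allele
   counting over all QC-passed individually genotyped samples (not from
   pool estimates).

Sample-level screening uses the *raw* call rate before clustering
(profiles: 0.90 / 0.95). Replicate concordance is summarised per
individual as the mismatch rate: loci with two different genotypes across
the individual's replicates, divided by the loci with at least two
non-missing calls for that individual — the denominator choice matters, as
mismatch is undefined where fewer than two calls exist.

# Evaluation

* **Agreement** regresses estimated on empirical frequencies per pool and
  reports the two-parameter adjusted R², `1 − (1 − R²)(n − 1)/(n − 2)`,
  plus the mean per-locus absolute difference (max of the pair minus min)
  and its standard error.
* **Error drivers**: OLS of the per-locus absolute difference on MAF,
  clustering-quality score and locus classification (SNP as reference
  level), with Gaussian t statistics. Collinear designs abort with a
  diagnostic rather than silently dropping terms.
* **Repeatability** is the intra-class correlation
  σ²~locus~/(σ²~locus~ + σ²~residual~) from a locus-random-intercept
  model. The contract is the variance ratio itself; the default backend is
  REML (`lme4`), with a parametric-bootstrap percentile interval. A
  Bayesian sampler would estimate the same estimand and is not required
  for it.
* **Reference-subset resampling** draws individuals without replacement
  (100 draws per size by default), recomputes cluster means from the
  sampled individuals' called genotypes only, re-estimates every
  pool × locus frequency, and records the proportion estimable, the mean
  adjusted R² against the full-panel empirical frequencies, and the mean
  absolute difference. Consecutive sizes are compared with Welch t-tests;
  no multiplicity correction is applied to this ladder of tests (raw p
  values are reported). Two documented choices: sampling is from the
  pooled population as a whole (a per-pool stratified mode exists behind
  `strata=`), and the estimability denominator is pool × locus per
  iteration, with replicate measurements first averaged to one θ per
  pool × locus. Inside the resampling a class mean is defined from one
  sampled call (`min_class_n = 1`, unlike the occupancy-2 rule of the
  mixture fit): the resampled means are anchored to an already validated
  clustering, so the single-point dispersion concern does not apply, and
  this makes estimability exactly the event "every genotype class was
  sampled", which has a closed hypergeometric form the tests verify
  against.
* **Rank correlations** (for the temporal-design analyses: year, fragment
  proportions, call rate, mismatch rate) use Spearman's rho with
  average-rank ties and the asymptotic t-approximation p value;
  constant inputs are reported as undefined rather than errored.

# The synthetic-data generator

The generator is the package's stand-in for array data and defines the
conditions under which everything is tested:

* **Panel**: requested counts of SNP / MSV-3 / monomorphic / discard-class
  loci. Cluster geometry defaults: SNP means (0.05, 0.50, 0.95); MSV-3
  means (0.05, 0.275, 0.50), honouring the ~0.5 θ span of duplicated loci;
  within-cluster sd 0.02. Only the span of MSV-3 loci is established
  knowledge; the positions are a package choice, configurable via
  `panel_geometry()`. MAFs are uniform on (0.05, 0.5) by default;
  monomorphic loci are fixed or segregate below MAF 0.01.
* **Individuals**: genotypes are Hardy–Weinberg draws from the locus
  frequency, fixed per individual; extraction/run replicates share the
  truth and draw independent noise and dropout. θ is Gaussian around the
  genotype's cluster mean with sd `theta_sd / quality`, truncated to
  [0, 1] (truncation by clamping creates negligible boundary atoms at
  these dispersions).
* **Degradation**: the expected proportion of DNA above 1000 bp follows a
  logistic decay in sample age (defaults: 0.75 fresh, 0.10 asymptote,
  midpoint 15 y, scale 6 y) with logit-normal sampling noise; `quality` is
  that proportion relative to the fresh-sample maximum. This reproduces
  the *direction* of the degradation phenomenon — older samples have less
  high-molecular-weight DNA and genotype worse — without claiming real
  coefficients. Where two cohorts of equal fragment profile genotype
  differently in real data (unknown chemical/biological factors), the
  model has no second factor and will not reproduce that.
* **Dropout** per record is `0.005 + 0.05 · (1 − quality)`, chosen so that
  a ~10-year-old cohort keeps raw call rates around 0.97–0.98 (almost all
  samples survive a 0.95 screen, as in a realistic pooling study) while
  35-year-old samples drift toward the 0.90 screen.
* **Pools**: the true pool frequency is the mean member dosage / 2; the
  pool θ is the *exact inverse* of the estimator's piecewise map plus
  truncated Gaussian noise (`noise_sd`, default 0.01). This makes
  estimator correctness testable by round trip — at zero noise the
  estimator must recover the frequency to machine precision — and makes
  `noise_sd` the single knob for pool-level estimation error. It also
  means the generator cannot, by construction, expose biases of the
  interpolation form itself; conclusions about real assay nonlinearity
  are out of its reach.
* **Designs**: `dataset1_design()` (4 cohort years × 4 fish × 2
  extractions × 2 runs = 64 samples of 16 individuals) and
  `dataset2_design()` (530 individuals in 4 pools of 87–161, each pool
  pipetted 3× and each pipetting run 3×, i.e. 9 replicate measurements
  per pool; default pool sizes 87/122/160/161). Contamination is a
  generated boolean only; contaminated samples are meant to be excluded
  upstream.

Passing tests on these synthetics therefore demonstrate internal
consistency (calling, QC arithmetic, estimator inversion, variance
components) and the qualitative degradation/panel-size behaviours; they do
not certify accuracy on any real array chemistry.

# Problem sizes and reproducibility

Every stochastic function takes a `seed` and is bit-reproducible given it.
The test suite's largest scenario — the reference-subset study — uses
2,000 analysable loci in array-like class proportions (1478 SNP, 328
MSV-3, 194 monomorphic), 500 pooled individuals in 4 pools, subset sizes
{10, 20, 30, 50} and 100 draws per size; this is ample for the monotone
trends and the closed-form estimability comparison while keeping the suite
fast. Parameter-recovery checks use 500 loci × 9 replicates
(repeatability) and 4,000 loci (error-driver regression).

# Limitations

* Clustering is one-dimensional in θ; two-dimensional (θ, R) clustering,
  copy-number inference and cross-chip batch normalisation are out of
  scope, as are unequal-contribution corrections for pool members and
  MSV-aware four-cluster estimation.
* The het-deviation filter's frequency-difference reading and the
  across-individuals MAF are documented choices where conventions differ;
  both thresholds are arguments.
* The degradation model is directional, not calibrated; its coefficients
  should not be quoted as biology.
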