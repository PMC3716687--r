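# allelopool

Estimation of population allele frequencies from **pooled DNA samples
genotyped on SNP arrays**, with the quality-control cascade needed to do
this reliably on degraded material (e.g. DNA from decades-old archived fish
scales), and an evaluation framework that quantifies how accurate and
repeatable the estimates are and how many individually genotyped reference
samples are required.

The package is aimed at population geneticists who want to "allelotype"
whole sample pools on one array assay each instead of genotyping every
individual, and who need to validate that strategy before applying it —
particularly in species with partially duplicated genomes (salmonids), where
multisite variants compress the assay's signal range and complicate
clustering.

## The method

A biallelic array assay summarises each sample x locus measurement by a
normalised total intensity *R* and an allelic intensity ratio θ ∈ [0, 1]
(0 = pure A signal, 1 = pure B signal). Individually genotyped reference
samples form three clusters in θ, with per-locus means θ̄_AA < θ̄_AB < θ̄_BB.
A pooled sample's θ moves continuously with its B-allele frequency, so the
pool frequency is estimated by piecewise-linear interpolation against the
cluster means:

```
freq_B = 0                                   if θ_pool ≤ θ̄_AA
freq_B = 0.5 · (θ_pool − θ̄_AA)/(θ̄_AB − θ̄_AA)   if θ̄_AA < θ_pool < θ̄_AB
freq_B = 0.5 + 0.5 · (θ_pool − θ̄_AB)/(θ̄_BB − θ̄_AB)   if θ̄_AB < θ_pool < θ̄_BB
freq_B = 1                                   if θ_pool ≥ θ̄_BB
```

If any of the three reference clusters is undefined (a genotype class never
sampled), the pool frequency at that locus is reported as *inestimable*
rather than guessed — the behaviour that drives the package's
reference-panel subsampling analysis ("how many reference individuals are
enough?").

Around this estimator the package provides:

* **`simulate_*`** — a synthetic-data generator for locus panels (SNP /
  MSV-3 / monomorphic / discard classes), Hardy–Weinberg individual
  genotypes with cluster-structured θ intensities, age-dependent DNA
  degradation (fragment-size profiles, dropout, noise), and pooled designs
  with pipetting × run replicates.
* **`cluster_loci()` / `call_genotypes()`** — a genotype-calling surrogate:
  ordered univariate Gaussian mixtures in θ with GenTrain-like per-locus
  separation scores and GenCall-like per-call confidence scores.
* **`qc_report()`** and friends — the locus QC cascade: classification
  filter, locus call rate (≥ 0.95), heterozygote excess/deficit versus the
  Hardy–Weinberg expectation (≤ 0.1), MAF > 0.05 polymorphism screen, and
  per-individual replicate mismatch rates.
* **`allelotype()` / `empirical_freqs()` / `agreement()` /
  `repeatability()` / `error_driver_glm()` / `subset_resampling()`** — the
  evaluation suite: estimated-vs-empirical agreement (adjusted R², mean
  absolute difference), variance-components repeatability of replicated
  estimates, an error-driver regression (MAF, clustering quality, locus
  class), and reference-subset resampling with Welch tests between sizes.
* **`run_pipeline()`** — a config-driven driver that chains
  simulate → call → qc → allelotype → evaluate and writes every
  intermediate table, a summary JSON and a log.

## Worked example

```r
library(allelopool)
library(dplyr)

panel  <- simulate_panel(n_snp = 300, n_msv3 = 60, n_mono = 40,
                         n_discard = 20, seed = 42)
design <- dataset2_design(pool_sizes = c(60, 80), seed = 43)
ind    <- simulate_individuals(panel, design$samples, seed = 44)
pools  <- simulate_pool_intensity(design$pools, design$pool_members,
                                  ind$truth, panel, noise_sd = 0.01, seed = 45)

keep   <- exclude_low_callrate_samples(ind$intensities, 0.95)
recs   <- ind$intensities |>
  filter(sample_id %in% keep$sample_id[keep$retained],
         locus_id %in% filter_by_classification(panel)$locus_id)
models <- cluster_loci(recs, panel = panel)
calls  <- call_genotypes(recs, models, call_threshold = 0.05)
qc     <- qc_report(calls, panel, models = models)
valid  <- qc$locus_id[qc$passed]

est <- allelotype(filter(pools, locus_id %in% valid), models) |> summarise_pool()
emp <- empirical_freqs(filter(calls, locus_id %in% valid), design$pool_members)
agreement(inner_join(est, emp, by = c("pool_id", "locus_id")) |>
            transmute(pool_id, empirical, estimated = freq_B))
```

```
# A tibble: 2 × 5
  pool_id n_loci adjusted_R2 mean_abs_diff se_abs_diff
  <chr>    <int>       <dbl>         <dbl>       <dbl>
1 P1         193       0.996       0.00676    0.000576
2 P2         193       0.997       0.00650    0.000400
```

Of 420 simulated loci, 344 pass QC; 193 per pool are both estimable and
empirically measurable. The estimated pool frequencies track the empirical
(allele-counting) frequencies with adjusted R² ≈ 0.996–0.997 and a mean
per-locus absolute difference below 0.007. Repeatability of the nine
replicate estimates per pool:

```r
repeatability(allelotype(filter(pools, locus_id %in% valid), models) |>
                filter(!is.na(freq_B)), interval = "none")
#> Repeatability = 0.9580
#>   among-locus variance 0.0232, residual variance 0.00102 (193 loci, 3474 estimates)
#>   REML random-intercept (lme4)
```

`plot_agreement()`, `plot_subset_results()` and `plot_cluster()` visualise
these results; `tidy()`/`glance()` methods cover the fitted objects.

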