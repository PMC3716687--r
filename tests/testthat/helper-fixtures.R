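# Small fixture builders shared across test files.

# One-row cluster-model tibble with the given means (NA allowed) and sds.
make_model <- function(locus_id = "L1", means = c(0.10, 0.45, 0.92),
                       sds = c(0.02, 0.02, 0.02), ns = c(30L, 40L, 30L)) {
  tibble::tibble(
    locus_id = locus_id,
    mean_AA = means[1], mean_AB = means[2], mean_BB = means[3],
    sd_AA = sds[1], sd_AB = sds[2], sd_BB = sds[3],
    n_AA = ns[1], n_AB = ns[2], n_BB = ns[3],
    n_obs = sum(ns, na.rm = TRUE),
    n_clusters = sum(!is.na(means)),
    gentrain_score = 0.8,
    unclusterable = FALSE
  )
}

# Call table for one locus from genotype counts (n_AA, n_AB, n_BB, n_nocall).
make_calls <- function(locus_id, counts, start_id = 1L) {
  genos <- rep(c("AA", "AB", "BB", "NOCALL"),
               times = c(counts, rep(0, 4 - length(counts))))
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_along(genos) + start_id - 1L),
    locus_id = locus_id,
    genotype = genos,
    gencall_score = ifelse(genos == "NOCALL", 0, 0.9)
  )
}

# Zero-noise, fully observed synthetic scenario: panel + individuals + pools.
zero_noise_scenario <- function(n_snp = 20, pool_sizes = c(20, 20),
                                seed = 42, maf = "uniform") {
  panel <- simulate_panel(n_snp, 0, 0, 0, maf_distribution = maf, seed = seed)
  panel$theta_sd <- 0
  design <- dataset2_design(pool_sizes = pool_sizes, seed = seed + 1L)
  design$samples$quality <- 1
  ind <- simulate_individuals(panel, design$samples, missing_base = 0,
                              missing_slope = 0, seed = seed + 2L)
  pools <- simulate_pool_intensity(design$pools, design$pool_members,
                                   ind$truth, panel, noise_sd = 0,
                                   seed = seed + 3L)
  list(panel = panel, design = design, truth = ind$truth,
       intensities = ind$intensities, pool_records = pools)
}
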