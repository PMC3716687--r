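test_that("panel generation honours class counts, geometry and MAF specs", {
  p <- simulate_panel(100, 30, 20, 10, seed = 1)
  expect_equal(as.vector(table(p$classification)[c("SNP", "MSV3", "MONO")]),
               c(100L, 30L, 20L))
  expect_equal(sum(!p$classification %in% c("SNP", "MSV3", "MONO")), 10)
  snp <- p[p$classification == "SNP", ]
  msv <- p[p$classification == "MSV3", ]
  expect_true(all(snp$theta_BB - snp$theta_AA >= 0.7))
  expect_true(all(msv$theta_BB - msv$theta_AA <= 0.55))
  expect_true(all(p$theta_AA < p$theta_AB & p$theta_AB < p$theta_BB))
  expect_true(all(p$design_score >= 0 & p$design_score <= 1))
  mono <- p[p$classification == "MONO", ]
  expect_true(all(pmin(mono$true_freq_B, 1 - mono$true_freq_B) < 0.01))

  # point-mass MAF
  pm <- simulate_panel(100, 0, 0, 0, maf_distribution = 0.3, seed = 7)
  expect_true(all(pm$true_freq_B %in% c(0.3, 0.7)))

  # empty request, invalid spec
  expect_equal(nrow(simulate_panel(0, 0, 0, 0, seed = 1)), 0)
  expect_error(simulate_panel(5, 0, 0, 0, maf_distribution = list(a = 1)),
               "maf_distribution")
  expect_error(simulate_panel(5, 0, 0, 0, maf_distribution = function(n) rep(2, n)),
               "0, 0.5")
})

test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  panel <- simulate_panel(1, 0, 0, 0, maf_distribution = 0.5, seed = 3)
  samples <- tibble::tibble(
    sample_id = sprintf("S%05d", 1:10000),
    individual_id = sprintf("S%05d", 1:10000),
    quality = 1
  )
  ind <- simulate_individuals(panel, samples, seed = 11)
  counts <- table(factor(ind$truth$dosage, levels = 0:2))
  p <- panel$true_freq_B
  expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  expect_gt(stats::chisq.test(counts, p = expected)$p.value, 0.01)
})

test_that("zero-noise intensities sit exactly on cluster means; replicates share truth", {
  panel <- simulate_panel(5, 2, 0, 0, seed = 5)
  panel$theta_sd <- 0
  samples <- tibble::tibble(
    sample_id = c("A_r1", "A_r2", "B_r1"),
    individual_id = c("A", "A", "B"),
    quality = 1
  )
  ind <- simulate_individuals(panel, samples, missing_base = 0,
                              missing_slope = 0, seed = 6)
  joined <- dplyr::inner_join(
    dplyr::inner_join(ind$intensities,
                      dplyr::mutate(samples, individual_id = individual_id),
                      by = "sample_id"),
    ind$truth, by = c("individual_id", "locus_id")
  )
  joined <- dplyr::inner_join(joined, panel, by = "locus_id")
  expected_theta <- with(joined, ifelse(dosage == 0, theta_AA,
                                        ifelse(dosage == 1, theta_AB, theta_BB)))
  expect_equal(joined$theta, expected_theta)

  # replicate samples of one individual read off the same genotype truth
  wide <- tidyr::pivot_wider(joined[, c("sample_id", "locus_id", "dosage")],
                             names_from = "sample_id", values_from = "dosage")
  expect_equal(wide$A_r1, wide$A_r2)

  # with noise, replicates share truth but draw independent thetas
  panel2 <- simulate_panel(50, 0, 0, 0, seed = 5)
  ind2 <- simulate_individuals(panel2, samples, missing_base = 0,
                               missing_slope = 0, seed = 6)
  th <- tidyr::pivot_wider(ind2$intensities[, c("sample_id", "locus_id", "theta")],
                           names_from = "sample_id", values_from = "theta")
  expect_false(isTRUE(all.equal(th$A_r1, th$A_r2)))
})

test_that("degradation model: proportion > 1000 bp declines with age, quality tracks it", {
  # noiseless mean function is maximal at age 0 and monotone in age
  pars0 <- degradation_params(noise_sd = 0)
  ages <- c(0, 5, 15, 25, 35)
  props <- simulate_degradation(2011 - ages, 2011, pars0, seed = 1)$prop_gt1000
  expect_true(all(diff(props) < 0))

  # stochastic version: means ordered for well-separated ages
  old <- simulate_degradation(rep(1976, 1000), 2011, seed = 2)
  new <- simulate_degradation(rep(2006, 1000), 2011, seed = 3)
  expect_lt(mean(old$prop_gt1000), mean(new$prop_gt1000))

  # quality is monotone in the realised proportion
  expect_true(all(diff(old$quality[order(old$prop_gt1000)]) >= 0))
  expect_true(all(old$quality > 0 & old$quality <= 1))
  expect_true(all(dplyr::select(old, dplyr::starts_with("frag_")) >= 0))

  # zero age effect: identical distributions at all ages
  parsnull <- degradation_params(age_effect = 0)
  a <- simulate_degradation(rep(1976, 50), 2011, parsnull, seed = 9)
  b <- simulate_degradation(rep(2006, 50), 2011, parsnull, seed = 9)
  expect_equal(a$prop_gt1000, b$prop_gt1000)

  expect_error(simulate_degradation(2020, 2011), "cohort_year")
})

test_that("pool forward map hits cluster means at f = 0, 0.5 and interpolates linearly", {
  sc <- zero_noise_scenario(n_snp = 1, pool_sizes = c(3, 3), seed = 2)
  # force an all-AA pool: overwrite truth dosages
  truth <- sc$truth
  truth$dosage <- 0L
  truth$genotype <- "AA"
  rec <- simulate_pool_intensity(sc$design$pools, sc$design$pool_members,
                                 truth, sc$panel, noise_sd = 0)
  expect_equal(unique(rec$theta), sc$panel$theta_AA)

  # f = 0.5 pool: all heterozygotes
  truth$dosage <- 1L
  truth$genotype <- "AB"
  rec <- simulate_pool_intensity(sc$design$pools, sc$design$pool_members,
                                 truth, sc$panel, noise_sd = 0)
  expect_equal(unique(rec$theta), sc$panel$theta_AB)

  # hand-evaluated interior point of the lower branch
  expect_equal(theta_from_freq(0.25, 0.10, 0.45, 0.92), 0.275)

  # empty pool errors
  expect_error(
    simulate_pool_intensity(
      tibble::tibble(pool_id = "PX", pipetting_rep = 1, run_rep = 1),
      sc$design$pool_members, truth, sc$panel
    ),
    "no members"
  )
})

test_that("fixed seeds reproduce every generator bit-for-bit", {
  p1 <- simulate_panel(30, 10, 5, 5, seed = 123)
  p2 <- simulate_panel(30, 10, 5, 5, seed = 123)
  expect_identical(p1, p2)

  d1 <- dataset2_design(pool_sizes = c(10, 12), seed = 9)
  d2 <- dataset2_design(pool_sizes = c(10, 12), seed = 9)
  expect_identical(d1, d2)

  i1 <- simulate_individuals(p1, d1$samples, seed = 4)
  i2 <- simulate_individuals(p2, d2$samples, seed = 4)
  expect_identical(i1, i2)

  r1 <- simulate_pool_intensity(d1$pools, d1$pool_members, i1$truth, p1, seed = 5)
  r2 <- simulate_pool_intensity(d2$pools, d2$pool_members, i2$truth, p2, seed = 5)
  expect_identical(r1, r2)
})

test_that("dataset designs reproduce their replicate structure", {
  d1 <- dataset1_design(seed = 1)
  expect_equal(nrow(d1), 64) # 16 fish x 2 extractions x 2 runs
  expect_equal(dplyr::n_distinct(d1$individual_id), 16)
  # runs of one extraction share the fragment profile
  per_ext <- d1 |>
    dplyr::group_by(individual_id, extraction_rep) |>
    dplyr::summarise(n_quality = dplyr::n_distinct(quality), .groups = "drop")
  expect_true(all(per_ext$n_quality == 1))

  d2 <- dataset2_design(seed = 2)
  expect_equal(nrow(d2$pools), 36) # 4 pools x 9 replicates
  expect_equal(nrow(d2$samples), 530)
  expect_true(all(dplyr::count(d2$pool_members, pool_id)$n >= 87))
  expect_true(all(dplyr::count(d2$pool_members, pool_id)$n <= 161))
})
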