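test_that("agreement reproduces closed-form least squares and mean differences", {
  # perfect agreement
  perfect <- tibble::tibble(pool_id = "P1", empirical = seq(0, 1, length.out = 100),
                            estimated = seq(0, 1, length.out = 100))
  a <- agreement(perfect)
  expect_equal(a$adjusted_R2, 1)
  expect_equal(a$mean_abs_diff, 0)

  # two pairs: mean of per-pair (max - min)
  two <- tibble::tibble(pool_id = "P1", empirical = c(0.2, 0.6),
                        estimated = c(0.25, 0.55))
  expect_equal(suppressWarnings(agreement(two))$mean_abs_diff, 0.05)

  # 10-pair fixture vs a hand-computed OLS oracle (explicit sums)
  set.seed(21)
  x <- runif(10)
  y <- 0.1 + 0.8 * x + rnorm(10, 0, 0.05)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  sse <- sum((y - alpha - beta * x)^2)
  sst <- sum((y - mean(y))^2)
  adj_oracle <- 1 - (1 - (1 - sse / sst)) * (10 - 1) / (10 - 2)
  a10 <- agreement(tibble::tibble(pool_id = "P", empirical = x, estimated = y))
  expect_equal(a10$adjusted_R2, adj_oracle, tolerance = 1e-10)
})

test_that("error-driver regression recovers a planted MAF effect", {
  set.seed(33)
  n <- 4000
  df <- tibble::tibble(
    maf = runif(n, 0, 0.5),
    gentrain_score = runif(n, 0.4, 1),
    classification = sample(c("SNP", "MSV3", "MONO"), n, replace = TRUE),
    abs_diff = 0.02 + 0.02 * maf + rnorm(n, 0, 1e-3)
  )
  fit <- error_driver_glm(df)
  co <- tidy(fit)
  expect_lt(abs(co$estimate[co$term == "maf"] - 0.02), 0.005)
  expect_true(all(c("classificationMSV3", "classificationMONO") %in% co$term))
  # SNP is the reference level: its dummy must not appear
  expect_false("classificationSNP" %in% co$term)
  expect_equal(nrow(glance(fit)), 1)

  # zero-variance response: all slopes exactly zero
  df0 <- df
  df0$abs_diff <- 0.01
  co0 <- suppressWarnings(tidy(error_driver_glm(df0)))
  expect_equal(co0$estimate[co0$term != "(Intercept)"],
               rep(0, nrow(co0) - 1))

  # one classification level: fits without dummies, warns
  df1 <- dplyr::filter(df, classification == "SNP")
  expect_warning(fit1 <- error_driver_glm(df1), "one classification")
  expect_false(any(grepl("classification", tidy(fit1)$term)))

  # collinear design errors with a diagnostic
  dfc <- df
  dfc$gentrain_score <- dfc$maf
  expect_error(error_driver_glm(dfc), "Collinear")
})

test_that("repeatability recovers variance ratios and respects invariances", {
  set.seed(55)
  n_loci <- 120
  mu <- rnorm(n_loci, 0.5, 0.3)
  df <- tidyr::crossing(locus_id = sprintf("L%03d", seq_len(n_loci)), rep = 1:6) |>
    dplyr::mutate(freq_B = mu[as.integer(factor(locus_id))] + rnorm(dplyr::n(), 0, 0.1))
  # true ratio 0.09 / (0.09 + 0.01) = 0.9
  r <- repeatability(df, interval = "none")
  expect_gt(r$repeatability, 0.8)
  expect_lt(r$repeatability, 0.97)

  # invariant to locus relabelling
  df_shuffled <- df
  relabel <- setNames(sample(unique(df$locus_id)), unique(df$locus_id))
  df_shuffled$locus_id <- unname(relabel[df_shuffled$locus_id])
  r2 <- repeatability(df_shuffled, interval = "none")
  expect_equal(r2$repeatability, r$repeatability, tolerance = 1e-6)

  # invariant to adding a constant
  df_shift <- dplyr::mutate(df, freq_B = freq_B + 10)
  r3 <- repeatability(df_shift, interval = "none")
  expect_equal(r3$repeatability, r$repeatability, tolerance = 1e-6)

  # all replicates identical within locus: repeatability ~ 1
  dfid <- tidyr::crossing(locus_id = sprintf("L%03d", 1:50), rep = 1:4) |>
    dplyr::mutate(freq_B = as.integer(factor(locus_id)) / 50)
  rid <- repeatability(dfid, interval = "none")
  expect_gt(rid$repeatability, 0.999)

  # pure noise, no locus effect: repeatability ~ 0
  set.seed(56)
  dfn <- tidyr::crossing(locus_id = sprintf("L%03d", 1:150), rep = 1:10) |>
    dplyr::mutate(freq_B = rnorm(dplyr::n()))
  rn <- repeatability(dfn, interval = "none")
  expect_lt(rn$repeatability, 0.1)

  # bootstrap interval brackets the point estimate
  rb <- repeatability(df, interval = "boot", nsim = 20, seed = 5)
  expect_lte(rb$interval_low, rb$repeatability)
  expect_gte(rb$interval_high, rb$repeatability)

  expect_error(
    repeatability(tibble::tibble(locus_id = "L1", freq_B = 0.3)),
    "replicates"
  )
})

test_that("rank correlations match a hand-computed tied-rank oracle", {
  inc <- tibble::tibble(a = 1:8, b = (1:8)^2)
  rc <- rank_correlations(inc, c("a", "b"))
  expect_equal(rc$rho, 1)

  dec <- tibble::tibble(a = 1:8, b = -(1:8))
  expect_equal(rank_correlations(dec, c("a", "b"))$rho, -1)

  # 8-point fixture with one tie: Pearson correlation of average ranks
  x <- c(1, 2, 2, 3, 4, 5, 6, 7)
  y <- c(2.0, 1.0, 3.5, 3.0, 5.0, 4.5, 6.5, 6.0)
  rank_avg <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  oracle <- {
    rx <- rank_avg(x); ry <- rank_avg(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  got <- rank_correlations(tibble::tibble(x = x, y = y), c("x", "y"))
  expect_equal(got$rho, oracle, tolerance = 1e-12)

  # constant vector: undefined rho, reported not errored
  const <- tibble::tibble(a = 1:8, b = rep(2, 8))
  rcc <- rank_correlations(const, c("a", "b"))
  expect_true(is.na(rcc$rho))
  expect_equal(rcc$status, "constant_vector")
})

test_that("subset resampling is exact on zero-noise balanced reference panels", {
  # 4 members per genotype class at every locus: any draw of 10 from 12
  # individuals contains all classes, so everything is estimable and exact
  loci <- sprintf("L%02d", 1:6)
  inds <- sprintf("I%02d", 1:12)
  geno <- rep(c("AA", "AB", "BB"), each = 4)
  means <- c(AA = 0.05, AB = 0.50, BB = 0.95)
  ref <- tidyr::crossing(sample_id = inds, locus_id = loci) |>
    dplyr::mutate(genotype = rep(geno, each = length(loci)),
                  theta = unname(means[genotype]))
  truth_f <- (4 + 2 * 4) / (2 * 12) # 0.5 at every locus
  pool_records <- tidyr::crossing(pool_id = c("P1", "P2"), locus_id = loci) |>
    dplyr::mutate(theta = theta_from_freq(truth_f, means["AA"], means["AB"],
                                          means["BB"]))
  empirical <- tidyr::crossing(pool_id = c("P1", "P2"), locus_id = loci) |>
    dplyr::mutate(empirical = truth_f)

  sr <- subset_resampling(ref, pool_records, empirical, sizes = c(10, 12),
                          n_iter = 10, seed = 3)
  expect_true(all(sr$results$prop_estimable == 1))
  expect_true(all(sr$results$mean_abs_diff == 0))
  # identical degenerate metric distributions: t = 0, p = 1 (the adjusted
  # R-squared is undefined here because every frequency is identical)
  cmp <- sr$comparisons[sr$comparisons$metric != "mean_adjusted_R2", ]
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p_value == 1))

  expect_error(
    subset_resampling(ref, pool_records, empirical, sizes = 13, n_iter = 2),
    "must not exceed"
  )
})

test_that("subset resampling Welch tests agree with a direct computation", {
  sc <- zero_noise_scenario(n_snp = 15, pool_sizes = c(12, 12), seed = 61)
  models <- cluster_from_truth(sc$intensities, sc$truth)
  calls <- call_genotypes(sc$intensities, models, 0.05)
  ref <- dplyr::inner_join(calls, sc$intensities,
                           by = c("sample_id", "locus_id"))
  rec <- simulate_pool_intensity(sc$design$pools, sc$design$pool_members,
                                 sc$truth, sc$panel, noise_sd = 0.02, seed = 62)
  emp <- empirical_freqs(calls, sc$design$pool_members)[
    , c("pool_id", "locus_id", "empirical")]
  sr <- subset_resampling(ref, rec, emp, sizes = c(6, 12), n_iter = 15,
                          seed = 8)
  for (met in unique(sr$comparisons$metric)) {
    lo <- sr$results[[met]][sr$results$subset_size == 6]
    hi <- sr$results[[met]][sr$results$subset_size == 12]
    oracle <- stats::t.test(hi, lo, var.equal = FALSE)
    row <- sr$comparisons[sr$comparisons$metric == met, ]
    expect_equal(row$t, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(row$p_value, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("re-cluster comparison finds swapped clusters and excludes absent loci", {
  set.seed(9)
  full <- tidyr::crossing(sample_id = sprintf("S%02d", 1:20),
                          locus_id = c("Lok", "Lswap", "Lonly_full")) |>
    dplyr::mutate(genotype = ifelse(
      locus_id == "Lswap",
      sample(c("AA", "BB"), dplyr::n(), replace = TRUE),
      sample(c("AA", "AB", "BB"), dplyr::n(), replace = TRUE)
    ))
  subset <- full |>
    dplyr::filter(locus_id != "Lonly_full") |>
    dplyr::mutate(genotype = ifelse(
      locus_id == "Lswap",
      c(AA = "BB", AB = "AB", BB = "AA")[genotype],
      genotype
    ))
  cmpres <- subset_recluster_compare(subset, full)
  expect_equal(cmpres$mismatch_fraction[cmpres$locus_id == "Lok"], 0)
  # all genotypes at the swapped locus are homozygous, so every one flips
  expect_equal(cmpres$mismatch_fraction[cmpres$locus_id == "Lswap"], 1)
  expect_true(cmpres$high_mismatch[cmpres$locus_id == "Lswap"])
  expect_equal(attr(cmpres, "excluded_loci"), "Lonly_full")

  # identical call sets: no mismatching loci
  same <- subset_recluster_compare(full, full)
  expect_true(all(same$n_mismatch == 0))

  disjoint <- dplyr::mutate(full, sample_id = paste0("X", sample_id))
  expect_error(subset_recluster_compare(disjoint, full), "share no samples")
})
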