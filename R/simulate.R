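#' Forward map from pool allele frequency to expected pool theta
#'
#' The exact inverse of [estimate_freq()]: a pool with B-allele frequency `f`
#' has expected theta on the piecewise-linear path AA-mean -> AB-mean (for
#' `f` in \[0, 0.5\]) -> BB-mean (for `f` in \[0.5, 1\]).
#'
#' @param freq_B Numeric vector of frequencies in \[0, 1\].
#' @param mean_AA,mean_AB,mean_BB Cluster mean thetas (recycled).
#' @return Expected pool theta.
#' @export
theta_from_freq <- function(freq_B, mean_AA, mean_AB, mean_BB) {
  stopifnot(all(freq_B >= 0 & freq_B <= 1, na.rm = TRUE))
  ifelse(freq_B <= 0.5,
         mean_AA + (freq_B / 0.5) * (mean_AB - mean_AA),
         mean_AB + ((freq_B - 0.5) / 0.5) * (mean_BB - mean_AB))
}

#' Simulate individual genotypes and array intensities
#'
#' Draws a fixed true genotype per individual and locus under Hardy-Weinberg
#' equilibrium at the locus's true B-allele frequency, then one intensity
#' record per (sample, locus): theta is Gaussian around the genotype's cluster
#' mean with standard deviation `theta_sd / quality` (lower-quality samples
#' are noisier), truncated to \[0, 1\]; records drop out (theta and R both
#' missing) with probability `missing_base + missing_slope * (1 - quality)`.
#' Replicate samples of the same individual share the genotype truth but draw
#' independent noise and missingness. R intensity is lognormal with a
#' quality-scaled median and is carried through file formats but never used by
#' the frequency estimator.
#'
#' @param panel Locus panel from [simulate_panel()].
#' @param samples Sample sheet with `sample_id`, `individual_id`, `quality`.
#' @param missing_base,missing_slope Dropout model intercept and slope.
#' @param seed Integer seed.
#' @return List with `truth` (tibble `individual_id`, `locus_id`, `dosage`
#'   in 0:2, `genotype`) and `intensities` (tibble `sample_id`, `locus_id`,
#'   `theta`, `r_intensity`).
#' @export
simulate_individuals <- function(panel, samples, missing_base = 0.005,
                                 missing_slope = 0.05, seed = NULL) {
  if (nrow(panel) == 0) abort("`panel` must contain at least one locus.")
  stopifnot(all(c("sample_id", "individual_id", "quality") %in% names(samples)),
            all(samples$quality > 0 & samples$quality <= 1))
  if (!is.null(seed)) set.seed(seed)

  inds <- unique(samples$individual_id)
  n_ind <- length(inds)
  n_loc <- nrow(panel)

  dosage <- rbinom(n_ind * n_loc, 2L, rep(panel$true_freq_B, each = n_ind))
  truth <- tibble(
    individual_id = rep(inds, times = n_loc),
    locus_id = rep(panel$locus_id, each = n_ind),
    dosage = dosage,
    genotype = GENOTYPES[dosage + 1L]
  )

  recs <- crossing(
    samples |> select("sample_id", "individual_id", "quality"),
    panel |> select("locus_id")
  ) |>
    left_join(truth |> select("individual_id", "locus_id", "dosage"),
              by = c("individual_id", "locus_id")) |>
    left_join(panel |> select("locus_id", "theta_AA", "theta_AB", "theta_BB",
                              "theta_sd"),
              by = "locus_id")
  mean_g <- with(recs, ifelse(dosage == 0L, theta_AA,
                              ifelse(dosage == 1L, theta_AB, theta_BB)))
  theta <- pmin(1, pmax(0, rnorm(nrow(recs), mean_g,
                                 recs$theta_sd / recs$quality)))
  r <- rlnorm(nrow(recs), meanlog = log(recs$quality), sdlog = 0.3)
  miss <- runif(nrow(recs)) < missing_base + missing_slope * (1 - recs$quality)
  theta[miss] <- NA_real_
  r[miss] <- NA_real_

  list(
    truth = truth,
    intensities = tibble(
      sample_id = recs$sample_id,
      locus_id = recs$locus_id,
      theta = theta,
      r_intensity = r
    )
  )
}

#' True pool B-allele frequencies from member genotypes
#'
#' @param pool_members Tibble `pool_id`, `individual_id`.
#' @param truth Genotype truth from [simulate_individuals()].
#' @return Tibble `pool_id`, `locus_id`, `true_freq` (mean member dosage / 2).
#' @export
pool_true_freqs <- function(pool_members, truth) {
  pool_members |>
    inner_join(truth, by = "individual_id", relationship = "many-to-many") |>
    group_by(.data$pool_id, .data$locus_id) |>
    summarise(true_freq = mean(.data$dosage) / 2, .groups = "drop")
}

#' Simulate pooled-sample array intensities
#'
#' For each pool replicate and locus, the true pool B-allele frequency (mean
#' member dosage / 2) is pushed through the piecewise-linear forward map
#' [theta_from_freq()] using the locus's true cluster geometry, and additive
#' Gaussian theta noise with standard deviation `noise_sd` is applied,
#' truncated to \[0, 1\]. `noise_sd` is the single knob controlling pool
#' estimation error.
#'
#' @param pools Pool replicate sheet (`pool_id`, `pipetting_rep`, `run_rep`).
#' @param pool_members Tibble `pool_id`, `individual_id`; every pool must
#'   have at least one member with genotype truth.
#' @param truth Genotype truth from [simulate_individuals()].
#' @param panel Locus panel (true cluster geometry).
#' @param noise_sd Theta noise standard deviation.
#' @param missing_rate Probability a pool record drops out.
#' @param seed Integer seed.
#' @return Tibble `pool_id`, `pipetting_rep`, `run_rep`, `locus_id`, `theta`,
#'   `r_intensity`.
#' @export
simulate_pool_intensity <- function(pools, pool_members, truth, panel,
                                    noise_sd = 0.01, missing_rate = 0,
                                    seed = NULL) {
  empty <- setdiff(pools$pool_id, pool_members$pool_id)
  if (length(empty) > 0) {
    abort(paste0("Pool(s) with no members: ", paste(empty, collapse = ", ")))
  }
  missing_truth <- setdiff(pool_members$individual_id, truth$individual_id)
  if (length(missing_truth) > 0) {
    abort("All pool members must have genotype truth.")
  }
  if (!is.null(seed)) set.seed(seed)

  tf <- pool_true_freqs(pool_members, truth)
  recs <- pools |>
    inner_join(tf, by = "pool_id", relationship = "many-to-many") |>
    inner_join(panel |> select("locus_id", "theta_AA", "theta_AB", "theta_BB"),
               by = "locus_id")
  theta <- theta_from_freq(recs$true_freq, recs$theta_AA, recs$theta_AB,
                           recs$theta_BB)
  if (noise_sd > 0) theta <- theta + rnorm(nrow(recs), 0, noise_sd)
  theta <- pmin(1, pmax(0, theta))
  r <- rlnorm(nrow(recs), meanlog = 0, sdlog = 0.3)
  if (missing_rate > 0) {
    miss <- runif(nrow(recs)) < missing_rate
    theta[miss] <- NA_real_
    r[miss] <- NA_real_
  }
  recs |>
    transmute(.data$pool_id, .data$pipetting_rep, .data$run_rep,
              .data$locus_id, theta = theta, r_intensity = r)
}
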