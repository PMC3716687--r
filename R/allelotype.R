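#' Estimate pool B-allele frequency from theta by piecewise-linear interpolation
#'
#' Converts the allelic intensity ratio (theta) of a pooled DNA sample into an
#' estimated B-allele frequency, relative to the mean theta of the three
#' genotype clusters (AA, AB, BB) fitted from individually genotyped reference
#' samples. The map is piecewise linear and continuous:
#'
#' * theta at or below the AA mean: frequency 0;
#' * between the AA and AB means: `0.5 * (theta - mAA) / (mAB - mAA)`;
#' * between the AB and BB means: `0.5 + 0.5 * (theta - mAB) / (mBB - mAB)`;
#' * at or above the BB mean: frequency 1.
#'
#' At theta exactly equal to the AB mean both interior branches agree and 0.5
#' is returned. All three cluster means must be defined: if any is `NA` the
#' estimate is inestimable and `NA` is returned (not an error), mirroring the
#' situation where a small reference panel never sampled one of the genotype
#' classes.
#'
#' @param theta_pool Numeric vector of pool theta values in \[0, 1\]; `NA`
#'   allowed (gives `NA`).
#' @param mean_AA,mean_AB,mean_BB Cluster mean thetas (recycled against
#'   `theta_pool`). Where all three are present they must be strictly
#'   increasing.
#' @return Numeric vector of estimated B-allele frequencies in \[0, 1\], `NA`
#'   where inestimable.
#' @examples
#' estimate_freq(c(0.05, 0.275, 0.45, 0.99), 0.10, 0.45, 0.92)
#' @export
estimate_freq <- function(theta_pool, mean_AA, mean_AB, mean_BB) {
  n <- max(length(theta_pool), length(mean_AA), length(mean_AB), length(mean_BB))
  theta_pool <- rep_len(theta_pool, n)
  mAA <- rep_len(mean_AA, n)
  mAB <- rep_len(mean_AB, n)
  mBB <- rep_len(mean_BB, n)

  if (any(theta_pool < 0 | theta_pool > 1, na.rm = TRUE)) {
    abort("`theta_pool` must lie in [0, 1].")
  }
  complete <- !is.na(mAA) & !is.na(mAB) & !is.na(mBB)
  bad <- complete & (mAA >= mAB | mAB >= mBB)
  if (any(bad)) {
    abort(sprintf(
      "Cluster means must be strictly increasing (AA < AB < BB); %d model(s) violate this.",
      sum(bad)
    ))
  }

  out <- rep(NA_real_, n)
  ok <- complete & !is.na(theta_pool)
  th <- theta_pool
  lower <- ok & th > mAA & th < mAB
  upper <- ok & th > mAB & th < mBB
  out[ok & th <= mAA] <- 0
  out[lower] <- 0.5 * (th[lower] - mAA[lower]) / (mAB[lower] - mAA[lower])
  out[ok & th == mAB] <- 0.5
  out[upper] <- 0.5 + 0.5 * (th[upper] - mAB[upper]) / (mBB[upper] - mAB[upper])
  out[ok & th >= mBB] <- 1
  out
}

#' Allelotype pooled intensity records against fitted cluster models
#'
#' Joins pool intensity records to per-locus cluster models and applies
#' [estimate_freq()] to each record. Records whose locus lacks one or more
#' cluster means, or whose theta is missing, are kept with `freq_B = NA` and an
#' explanatory `reason`.
#'
#' @param pool_records Tibble of pool intensity records with at least
#'   `pool_id`, `locus_id`, `theta`; replicate columns (`pipetting_rep`,
#'   `run_rep`) are carried through when present.
#' @param models Cluster-model tibble as returned by [cluster_loci()]
#'   (columns `locus_id`, `mean_AA`, `mean_AB`, `mean_BB`, ...).
#' @return Tibble with the identifying columns of `pool_records` plus `theta`,
#'   `freq_B` (`NA` when inestimable) and `reason` (`"ok"`,
#'   `"missing_cluster"`, `"missing_theta"`, `"unknown_locus"`).
#' @export
allelotype <- function(pool_records, models) {
  stopifnot(all(c("pool_id", "locus_id", "theta") %in% names(pool_records)))
  keep <- intersect(
    c("pool_id", "locus_id", "pipetting_rep", "run_rep", "theta"),
    names(pool_records)
  )
  est <- pool_records |>
    select(all_of(keep)) |>
    left_join(
      select(models, "locus_id", "mean_AA", "mean_AB", "mean_BB"),
      by = "locus_id"
    ) |>
    mutate(
      known = .data$locus_id %in% models$locus_id,
      freq_B = estimate_freq(.data$theta, .data$mean_AA, .data$mean_AB, .data$mean_BB),
      reason = case_when(
        !known ~ "unknown_locus",
        is.na(.data$theta) ~ "missing_theta",
        is.na(.data$mean_AA) | is.na(.data$mean_AB) | is.na(.data$mean_BB) ~
          "missing_cluster",
        TRUE ~ "ok"
      )
    )
  est |> select(all_of(keep), "freq_B", "reason")
}

#' Empirical B-allele frequency by allele counting
#'
#' The "empirical" frequency of a pool is computed from the individual
#' genotypes of its constituent members: `(#AB + 2 * #BB) / (2 * #called)`,
#' with no-calls excluded from both numerator and denominator.
#'
#' @param genotypes Character vector of genotype calls (`"AA"`, `"AB"`,
#'   `"BB"`, `"NOCALL"` or `NA`).
#' @return B-allele frequency in \[0, 1\], or `NA` if no genotype was called.
#' @examples
#' empirical_freq(c("AA", "AB", "BB", "BB")) # 0.625
#' @export
empirical_freq <- function(genotypes) {
  g <- genotypes[!is.na(genotypes) & genotypes != "NOCALL"]
  if (length(g) == 0) return(NA_real_)
  bad <- setdiff(unique(g), GENOTYPES)
  if (length(bad) > 0) {
    abort(paste0("Unknown genotype value(s): ", paste(bad, collapse = ", ")))
  }
  (sum(g == "AB") + 2 * sum(g == "BB")) / (2 * length(g))
}

#' Empirical per-pool, per-locus allele frequencies
#'
#' @param calls Genotype-call tibble (`sample_id`, `locus_id`, `genotype`);
#'   an `individual_id` column is used for the membership join when present.
#' @param pool_members Tibble mapping `pool_id` to member `individual_id`.
#' @return Tibble `pool_id`, `locus_id`, `empirical` (`NA` if no member was
#'   called), `n_called`.
#' @export
empirical_freqs <- function(calls, pool_members) {
  stopifnot(all(c("pool_id", "individual_id") %in% names(pool_members)))
  id_col <- if ("individual_id" %in% names(calls)) "individual_id" else "sample_id"
  pool_members |>
    inner_join(calls, by = setNames(id_col, "individual_id"),
               relationship = "many-to-many") |>
    group_by(.data$pool_id, .data$locus_id) |>
    summarise(
      empirical = empirical_freq(.data$genotype),
      n_called = sum(!is.na(.data$genotype) & .data$genotype != "NOCALL"),
      .groups = "drop"
    )
}

#' Average replicate frequency estimates within each pool and locus
#'
#' @param estimates Output of [allelotype()].
#' @return Tibble `pool_id`, `locus_id`, `freq_B` (mean over defined replicate
#'   estimates; `NA` with `reason = "all_inestimable"` if none was defined),
#'   `n_replicates`, `n_inestimable`.
#' @export
summarise_pool <- function(estimates) {
  estimates |>
    group_by(.data$pool_id, .data$locus_id) |>
    summarise(
      n_replicates = n(),
      n_inestimable = sum(is.na(.data$freq_B)),
      freq_B = if (all(is.na(.data$freq_B))) NA_real_ else
        mean(.data$freq_B, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(reason = if_else(is.na(.data$freq_B), "all_inestimable", "ok")) |>
    select("pool_id", "locus_id", "freq_B", "n_replicates", "n_inestimable", "reason")
}
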