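#' Replicate design for an individual-genotyping repeatability study
#'
#' Builds the sample sheet for a temporal repeatability design: `fish_per_year`
#' individuals from each sampling year, each DNA-extracted `n_extractions`
#' times, each extraction genotyped `n_runs` times. The default (4 fish from
#' each of 4 years, 2 extractions, 2 runs) yields 64 genotyped samples from 16
#' individuals. Degradation (fragment profile and quality) is drawn once per
#' extraction; genotyping runs of the same extraction share it.
#'
#' @param years Integer vector of cohort (sampling) years.
#' @param fish_per_year,n_extractions,n_runs Design counts.
#' @param reference_year Year of extraction/genotyping.
#' @param params Degradation parameters, see [degradation_params()].
#' @param contamination_rate Probability a sample is flagged contaminated
#'   (contaminated samples are excluded upstream of any analysis).
#' @param seed Integer seed.
#' @return Tibble with one row per genotyped sample: `sample_id`,
#'   `individual_id`, `cohort_year`, `extraction_rep`, `run_rep`, fragment
#'   bins, `prop_gt1000`, `quality`, `contaminated`.
#' @export
dataset1_design <- function(years = c(1976, 1987, 1996, 2006),
                            fish_per_year = 4, n_extractions = 2, n_runs = 2,
                            reference_year = 2011,
                            params = degradation_params(),
                            contamination_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fish <- crossing(cohort_year = years, fish = seq_len(fish_per_year)) |>
    mutate(individual_id = sprintf("F%d_%02d", .data$cohort_year, .data$fish))
  extractions <- crossing(fish, extraction_rep = seq_len(n_extractions))
  deg <- simulate_degradation(extractions$cohort_year, reference_year, params)
  extractions <- bind_cols(extractions, select(deg, -"cohort_year")) |>
    mutate(contaminated = runif(n()) < contamination_rate)
  crossing(extractions, run_rep = seq_len(n_runs)) |>
    mutate(sample_id = sprintf("%s_e%d_r%d", .data$individual_id,
                               .data$extraction_rep, .data$run_rep)) |>
    select("sample_id", "individual_id", "cohort_year", "extraction_rep",
           "run_rep", starts_with("frag_"), "prop_gt1000", "quality",
           "contaminated")
}

#' Pooling design for an allelotyping accuracy study
#'
#' Builds the sample sheet, pool membership and pool replicate sheet for a
#' pooled-DNA design: individuals from recent cohorts are each genotyped once
#' and assigned to one of several DNA pools; every pool is pipetted
#' `n_pipetting` times and each pipetting replicate genotyped `n_runs` times
#' (default 3 x 3 = 9 replicate measurements per pool). The default pool
#' sizes (87, 122, 160, 161) place 530 individuals into 4 pools of between 87
#' and 161 members.
#'
#' @param pool_sizes Integer vector, one entry per pool; the sum is the number
#'   of individuals.
#' @param years Cohort years sampled uniformly across individuals.
#' @param n_pipetting,n_runs Replicate counts per pool.
#' @param reference_year,params,contamination_rate,seed As in
#'   [dataset1_design()].
#' @return List of three tibbles: `samples` (one genotyped sample per
#'   individual, `sample_id == individual_id`), `pools` (one row per pool
#'   replicate: `pool_id`, `pipetting_rep`, `run_rep`), and `pool_members`
#'   (`pool_id`, `individual_id`).
#' @export
dataset2_design <- function(pool_sizes = c(87, 122, 160, 161),
                            years = 2001:2003, n_pipetting = 3, n_runs = 3,
                            reference_year = 2011,
                            params = degradation_params(),
                            contamination_rate = 0, seed = NULL) {
  stopifnot(all(pool_sizes >= 1))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(pool_sizes)
  cohort_year <- sample(rep_len(years, n))
  deg <- simulate_degradation(cohort_year, reference_year, params)
  samples <- tibble(
    sample_id = sprintf("I%04d", seq_len(n)),
    individual_id = sprintf("I%04d", seq_len(n)),
    cohort_year = cohort_year,
    extraction_rep = 1L,
    run_rep = 1L
  ) |>
    bind_cols(select(deg, -"cohort_year")) |>
    mutate(contaminated = runif(n) < contamination_rate)

  pool_ids <- sprintf("P%d", seq_along(pool_sizes))
  pool_members <- tibble(
    pool_id = rep(pool_ids, pool_sizes),
    individual_id = samples$individual_id
  )
  pools <- crossing(
    pool_id = pool_ids,
    pipetting_rep = seq_len(n_pipetting),
    run_rep = seq_len(n_runs)
  )
  list(samples = samples, pools = pools, pool_members = pool_members)
}
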