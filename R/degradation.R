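#' Parameters of the DNA-degradation model
#'
#' Archived dry-stored tissue (e.g. fish scales) degrades with age: the
#' proportion of DNA in fragments longer than 1000 bp declines as samples get
#' older, and genotyping quality tracks that proportion. The model here is a
#' logistic decay of the expected high-molecular-weight proportion with sample
#' age, with logit-normal sampling noise; the five Bioanalyzer-style fragment
#' bins (0-500, 500-1000, 1000-5000, 5000-17000, > 17000 bp, in ng/ul) are
#' then allocated consistently with that proportion.
#'
#' @param prop_max,prop_min Expected proportion of DNA > 1000 bp for a fresh
#'   sample and the asymptote for very old samples.
#' @param midpoint_age,scale_age Age (years) at the logistic midpoint and the
#'   logistic scale.
#' @param age_effect Multiplier on the age term; 0 removes the age effect
#'   entirely (all ages share one distribution).
#' @param noise_sd Standard deviation of the logit-scale sampling noise.
#' @param total_mean,total_cv Mean and coefficient of variation of total
#'   measured DNA concentration (ng/ul), age-independent.
#' @return Named list of parameters.
#' @export
degradation_params <- function(prop_max = 0.75, prop_min = 0.10,
                               midpoint_age = 15, scale_age = 6,
                               age_effect = 1, noise_sd = 0.3,
                               total_mean = 15, total_cv = 0.25) {
  stopifnot(prop_max > prop_min, prop_min > 0, prop_max < 1,
            scale_age > 0, noise_sd >= 0, total_mean > 0, total_cv >= 0)
  as.list(environment())
}

#' Simulate fragment-size profiles and genotyping quality for aged samples
#'
#' For each sample age (`reference_year - cohort_year`), draws a fragment-size
#' profile and derives a genotyping `quality` in (0, 1\]: the realised
#' proportion of DNA > 1000 bp relative to the fresh-sample expectation
#' (`prop_max`), capped at 1. Quality is therefore a monotone function of the
#' high-molecular-weight proportion, and its expectation is non-increasing in
#' sample age.
#'
#' @param cohort_year Integer vector of sampling years (one per sample).
#' @param reference_year Year of DNA extraction; must be >= all cohort years.
#' @param params See [degradation_params()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Tibble with one row per sample: `cohort_year`, the five fragment
#'   bins `frag_0_500` ... `frag_gt_17000` (ng/ul), `prop_gt1000`, `quality`.
#' @export
simulate_degradation <- function(cohort_year, reference_year,
                                 params = degradation_params(), seed = NULL) {
  if (any(cohort_year > reference_year)) {
    abort("`cohort_year` cannot be later than `reference_year`.")
  }
  if (!is.null(seed)) set.seed(seed)
  age <- reference_year - cohort_year
  n <- length(age)

  mean_prop <- params$prop_min + (params$prop_max - params$prop_min) *
    plogis(-params$age_effect * (age - params$midpoint_age) / params$scale_age)
  prop <- plogis(qlogis(mean_prop) + rnorm(n, 0, params$noise_sd))

  sdlog <- sqrt(log(1 + params$total_cv^2))
  total <- rlnorm(n, log(params$total_mean) - sdlog^2 / 2, sdlog)

  # Split mass below / above 1000 bp, then subdivide each side with mildly
  # noisy weights (Dirichlet via gamma draws).
  split2 <- function(k, shape) {
    w <- matrix(stats::rgamma(n * k, shape = shape), nrow = n)
    w / rowSums(w)
  }
  low <- split2(2, c(3, 2))    # 0-500, 500-1000
  high <- split2(3, c(3, 2, 1)) # 1000-5000, 5000-17000, >17000

  tibble(
    cohort_year = cohort_year,
    frag_0_500 = total * (1 - prop) * low[, 1],
    frag_500_1000 = total * (1 - prop) * low[, 2],
    frag_1000_5000 = total * prop * high[, 1],
    frag_5000_17000 = total * prop * high[, 2],
    frag_gt_17000 = total * prop * high[, 3],
    prop_gt1000 = prop,
    quality = pmin(1, prop / params$prop_max)
  )
}
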