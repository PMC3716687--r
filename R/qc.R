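#' Retain analysable locus classes
#'
#' Array manifests classify loci by how they segregate; only diploid SNPs,
#' MSV-3 loci (polymorphism on a single paralogue of a duplicated region) and
#' monomorphic loci are analysable. Loci classified UNKNOWN, MSV5, PSV, MITO
#' or FAILED are discarded.
#'
#' @param panel Locus panel/manifest with a `classification` column.
#' @return The retained rows of `panel`.
#' @export
filter_by_classification <- function(panel) {
  bad <- setdiff(unique(panel$classification), LOCUS_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Unknown locus classification(s): ", paste(bad, collapse = ", ")))
  }
  filter(panel, .data$classification %in% RETAINED_CLASSES)
}

# Per-locus genotype-count statistics from a call table.
locus_genotype_stats <- function(calls) {
  calls |>
    group_by(.data$locus_id) |>
    summarise(
      n_total = n(),
      n_called = sum(.data$genotype %in% GENOTYPES),
      n_AA = sum(.data$genotype == "AA"),
      n_AB = sum(.data$genotype == "AB"),
      n_BB = sum(.data$genotype == "BB"),
      .groups = "drop"
    ) |>
    mutate(
      call_rate = .data$n_called / .data$n_total,
      p_B = if_else(.data$n_called > 0,
                    (.data$n_AB + 2 * .data$n_BB) / (2 * .data$n_called),
                    NA_real_),
      maf = pmin(.data$p_B, 1 - .data$p_B),
      het_obs = if_else(.data$n_called > 0, .data$n_AB / .data$n_called,
                        NA_real_),
      het_exp = 2 * .data$p_B * (1 - .data$p_B)
    )
}

#' Locus call-rate filter
#'
#' A locus passes when its call rate over quality-retained samples (called /
#' (called + no-call)) is at or above `threshold`; loci strictly below it are
#' discarded.
#'
#' @param calls Genotype-call tibble.
#' @param threshold Minimum call rate (default 0.95).
#' @return Tibble `locus_id`, `call_rate`, `pass`.
#' @export
locus_call_rate_filter <- function(calls, threshold = 0.95) {
  if (nrow(calls) == 0) abort("`calls` is empty.")
  locus_genotype_stats(calls) |>
    transmute(.data$locus_id, .data$call_rate,
              pass = .data$call_rate >= threshold)
}

#' Heterozygote excess/deficit filter
#'
#' Computes the observed heterozygote frequency among called genotypes and
#' its Hardy-Weinberg expectation `2 p (1 - p)` (with `p` the B-allele
#' frequency from genotype counts); a locus fails when the absolute deviation
#' exceeds `threshold`. In salmonids, residual polymorphism on both
#' paralogues of a duplicated locus inflates apparent heterozygosity, which
#' this filter catches. When re-analysing with small reference panels the
#' threshold is conventionally relaxed to 0.5 because the statistic inflates
#' at small sample sizes.
#'
#' @param calls Genotype-call tibble.
#' @param threshold Maximum |het_obs - het_exp| (default 0.1).
#' @return Tibble `locus_id`, `het_obs`, `het_exp`, `het_dev`, `pass`
#'   (`NA` for loci with no called genotype).
#' @export
het_deviation_filter <- function(calls, threshold = 0.1) {
  locus_genotype_stats(calls) |>
    transmute(
      .data$locus_id, .data$het_obs, .data$het_exp,
      het_dev = abs(.data$het_obs - .data$het_exp),
      pass = .data$het_dev <= threshold
    )
}

#' Polymorphic loci by minor allele frequency
#'
#' @param calls Genotype-call tibble (restrict to QC-passed loci first).
#' @param maf_threshold Loci with MAF strictly above this are polymorphic.
#' @return Character vector of polymorphic locus ids.
#' @export
polymorphic_set <- function(calls, maf_threshold = 0.05) {
  st <- locus_genotype_stats(calls)
  st$locus_id[!is.na(st$maf) & st$maf > maf_threshold]
}

#' Full locus quality-control cascade
#'
#' Applies the locus filters in one pass: discard-class loci (`BAD_CLASS`),
#' loci with call rate strictly below `locus_callrate`
#' (`LOW_LOCUS_CALLRATE`), loci whose heterozygote frequency deviates from
#' the Hardy-Weinberg expectation by more than `het_threshold`
#' (`HET_DEVIATION`), and loci flagged at cluster review (`FLAGGED_CLUSTER`,
#' only when `models` is supplied). The filters are independent predicates,
#' so the pass set does not depend on their order.
#'
#' @param calls Genotype-call tibble over QC-retained samples.
#' @param panel Locus panel/manifest (for classifications). Panel loci with
#'   no calls at all get call rate 0.
#' @param models Optional cluster-model tibble for review flags.
#' @param locus_callrate,het_threshold Filter thresholds.
#' @param min_separation Cluster-review separation threshold, see
#'   [cluster_flags()].
#' @return Tibble, one row per panel locus: `locus_id`, `classification`,
#'   `call_rate`, `p_B`, `maf`, `het_obs`, `het_exp`, `fail_reasons`
#'   (list-column of character vectors), `passed`.
#' @export
qc_report <- function(calls, panel, models = NULL,
                      locus_callrate = 0.95, het_threshold = 0.1,
                      min_separation = 2) {
  bad <- setdiff(unique(panel$classification), LOCUS_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Unknown locus classification(s): ", paste(bad, collapse = ", ")))
  }
  st <- locus_genotype_stats(calls)
  rep <- panel |>
    select("locus_id", "classification") |>
    left_join(st, by = "locus_id") |>
    mutate(
      call_rate = if_else(is.na(.data$call_rate), 0, .data$call_rate),
      het_dev = abs(.data$het_obs - .data$het_exp)
    )
  if (!is.null(models)) {
    fl <- cluster_flags(models, min_separation = min_separation)
    rep <- left_join(rep, select(fl, "locus_id", "flagged"), by = "locus_id") |>
      mutate(flagged = if_else(is.na(.data$flagged), FALSE, .data$flagged))
  } else {
    rep$flagged <- FALSE
  }
  rep |>
    mutate(
      fail_reasons = pmap(
        list(.data$classification, .data$call_rate, .data$het_dev,
             .data$flagged),
        function(cl, cr, hd, fl) {
          c(
            if (!cl %in% RETAINED_CLASSES) "BAD_CLASS",
            if (cr < locus_callrate) "LOW_LOCUS_CALLRATE",
            if (!is.na(hd) && hd > het_threshold) "HET_DEVIATION",
            if (fl) "FLAGGED_CLUSTER"
          )
        }
      ),
      passed = lengths(.data$fail_reasons) == 0
    ) |>
    select("locus_id", "classification", "call_rate", "p_B", "maf",
           "het_obs", "het_exp", "fail_reasons", "passed")
}

#' Cross-replicate genotyping metrics per individual
#'
#' For an individual genotyped as several replicate samples, the mismatch
#' rate is the proportion of loci at which two different genotypes were
#' recorded across the replicates, out of the loci with at least two
#' non-missing calls for that individual (mismatch is undefined elsewhere).
#'
#' @param calls Genotype-call tibble.
#' @param samples Sample sheet mapping `sample_id` to `individual_id`.
#' @return Tibble `individual_id`, `n_replicates`, `n_loci_compared`,
#'   `n_mismatch`, `mismatch_rate` (`NA` for single-replicate individuals).
#' @export
replicate_metrics <- function(calls, samples) {
  d <- calls |>
    inner_join(select(samples, "sample_id", "individual_id"), by = "sample_id")
  reps <- d |>
    distinct(.data$individual_id, .data$sample_id) |>
    count(.data$individual_id, name = "n_replicates")
  per_locus <- d |>
    filter(.data$genotype %in% GENOTYPES) |>
    group_by(.data$individual_id, .data$locus_id) |>
    summarise(n_calls = n(), n_geno = n_distinct(.data$genotype),
              .groups = "drop") |>
    filter(.data$n_calls >= 2)
  mism <- per_locus |>
    group_by(.data$individual_id) |>
    summarise(n_loci_compared = n(), n_mismatch = sum(.data$n_geno > 1),
              .groups = "drop")
  reps |>
    left_join(mism, by = "individual_id") |>
    mutate(
      n_loci_compared = if_else(is.na(.data$n_loci_compared), 0L,
                                .data$n_loci_compared),
      n_mismatch = if_else(is.na(.data$n_mismatch), 0L, .data$n_mismatch),
      mismatch_rate = if_else(
        .data$n_replicates < 2 | .data$n_loci_compared == 0, NA_real_,
        .data$n_mismatch / .data$n_loci_compared
      )
    )
}
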