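#' Reference-panel subset resampling for pool allele-frequency estimation
#'
#' How many individually genotyped reference samples are enough? For each
#' subset size, individuals are repeatedly sampled without replacement from
#' the reference panel; on each draw the genotype-cluster mean thetas are
#' recomputed from the sampled individuals' called genotypes only, and every
#' pool x locus frequency is re-estimated against those means with the
#' piecewise estimator. A locus is estimable in a draw only when all three
#' genotype classes are represented (with at least `min_class_n` sampled
#' calls each) and the resulting means are strictly increasing.
#'
#' Per draw the function records the proportion of pool x locus frequencies
#' that could be estimated, the mean (over pools) adjusted R-squared against
#' the full-panel empirical frequencies, and the mean absolute difference
#' from them. Consecutive subset sizes are compared with Welch two-sample
#' t-tests (unequal variances) on each metric.
#'
#' @param ref Reference calls with thetas: tibble `sample_id`, `locus_id`,
#'   `theta`, `genotype` (`NOCALL`/missing rows are ignored).
#' @param pool_records Pool intensity records (`pool_id`, `locus_id`,
#'   `theta`); replicate rows are averaged to one theta per pool x locus.
#' @param empirical Full-panel empirical frequencies (`pool_id`, `locus_id`,
#'   `empirical`).
#' @param sizes Integer vector of subset sizes; each must not exceed the
#'   number of reference individuals.
#' @param n_iter Draws per size (default 100).
#' @param min_class_n Minimum sampled calls per genotype class for its mean
#'   to be defined (default 1).
#' @param strata Optional tibble `sample_id`, `stratum`: when given, each
#'   draw allocates the subset size across strata proportionally to stratum
#'   size (e.g. per-pool stratified sampling).
#' @param seed Integer seed.
#' @return List of class `subset_result`:
#'   * `results`: tibble `subset_size`, `iteration`, `prop_estimable`,
#'     `mean_adjusted_R2`, `mean_abs_diff`, `seed`;
#'   * `comparisons`: Welch t-tests between consecutive sizes per metric;
#'   * `locus_estimable`: per size x locus, the number of draws in which the
#'     locus was estimable.
#' @export
subset_resampling <- function(ref, pool_records, empirical, sizes,
                              n_iter = 100, min_class_n = 1, strata = NULL,
                              seed = NULL) {
  stopifnot(all(c("sample_id", "locus_id", "theta", "genotype") %in% names(ref)))
  if (!is.null(seed)) set.seed(seed)

  inds <- unique(ref$sample_id)
  n_ref <- length(inds)
  if (any(sizes > n_ref)) {
    abort(sprintf("Subset sizes must not exceed the %d reference individuals.",
                  n_ref))
  }

  pool_theta <- pool_records |>
    group_by(.data$pool_id, .data$locus_id) |>
    summarise(theta = if (all(is.na(.data$theta))) NA_real_ else
      mean(.data$theta, na.rm = TRUE), .groups = "drop")
  loci <- sort(unique(pool_theta$locus_id))
  pools <- sort(unique(pool_theta$pool_id))
  L <- length(loci); P <- length(pools)

  TP <- matrix(NA_real_, P, L, dimnames = list(pools, loci))
  TP[cbind(match(pool_theta$pool_id, pools),
           match(pool_theta$locus_id, loci))] <- pool_theta$theta
  EMP <- matrix(NA_real_, P, L)
  ei <- cbind(match(empirical$pool_id, pools), match(empirical$locus_id, loci))
  keep <- complete.cases(ei)
  EMP[ei[keep, , drop = FALSE]] <- empirical$empirical[keep]

  # Per-genotype indicator and theta-sum matrices over reference individuals.
  usable <- ref$genotype %in% GENOTYPES & !is.na(ref$theta) &
    ref$locus_id %in% loci
  rr <- ref[usable, ]
  ri <- match(rr$sample_id, inds)
  li <- match(rr$locus_id, loci)
  cnt <- sums <- list()
  for (g in GENOTYPES) {
    M <- matrix(0, n_ref, L)
    Tg <- matrix(0, n_ref, L)
    sel <- rr$genotype == g
    M[cbind(ri[sel], li[sel])] <- 1
    Tg[cbind(ri[sel], li[sel])] <- rr$theta[sel]
    cnt[[g]] <- M
    sums[[g]] <- Tg
  }

  if (!is.null(strata)) {
    stopifnot(all(c("sample_id", "stratum") %in% names(strata)))
    strat_idx <- split(match(strata$sample_id, inds), strata$stratum)
    strat_idx <- lapply(strat_idx, function(i) i[!is.na(i)])
    strat_n <- lengths(strat_idx)
  }
  draw_subset <- function(size) {
    if (is.null(strata)) return(sample(n_ref, size))
    alloc <- floor(size * strat_n / sum(strat_n))
    rem <- size - sum(alloc)
    if (rem > 0) {
      extra <- sample(length(alloc), rem, prob = strat_n / sum(strat_n))
      alloc[extra] <- alloc[extra] + 1
    }
    unlist(purrr::map2(strat_idx, alloc, function(i, k) sample(i, min(k, length(i)))))
  }

  denom <- sum(!is.na(TP))
  results <- vector("list", length(sizes) * n_iter)
  est_count <- matrix(0L, length(sizes), L,
                      dimnames = list(as.character(sizes), loci))
  row <- 0L
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    for (it in seq_len(n_iter)) {
      idx <- draw_subset(size)
      mg <- lapply(GENOTYPES, function(g) {
        k <- colSums(cnt[[g]][idx, , drop = FALSE])
        s <- colSums(sums[[g]][idx, , drop = FALSE])
        ifelse(k >= min_class_n & k > 0, s / k, NA_real_)
      })
      mAA <- mg[[1]]; mAB <- mg[[2]]; mBB <- mg[[3]]
      ok <- !is.na(mAA) & !is.na(mAB) & !is.na(mBB) &
        mAA < mAB & mAB < mBB
      mAA[!ok] <- NA_real_; mAB[!ok] <- NA_real_; mBB[!ok] <- NA_real_
      est_count[si, ] <- est_count[si, ] + ok

      fhat <- matrix(NA_real_, P, L)
      for (p in seq_len(P)) {
        fhat[p, ] <- estimate_freq(TP[p, ], mAA, mAB, mBB)
      }

      adj <- vapply(seq_len(P), function(p) {
        pair_ok <- !is.na(fhat[p, ]) & !is.na(EMP[p, ])
        adj_r2(EMP[p, pair_ok], fhat[p, pair_ok])
      }, numeric(1))
      diffs <- abs(fhat - EMP)

      row <- row + 1L
      results[[row]] <- tibble(
        subset_size = size, iteration = it,
        prop_estimable = sum(!is.na(fhat)) / denom,
        mean_adjusted_R2 = mean(adj, na.rm = TRUE),
        mean_abs_diff = mean(diffs, na.rm = TRUE)
      )
    }
  }
  results <- list_rbind(results) |> mutate(seed = seed %||% NA_integer_)

  metrics <- c("prop_estimable", "mean_adjusted_R2", "mean_abs_diff")
  comparisons <- if (length(sizes) >= 2) {
    crossing(metric = metrics, i = seq_len(length(sizes) - 1)) |>
      pmap(function(metric, i) {
        lo <- results[[metric]][results$subset_size == sizes[i]]
        hi <- results[[metric]][results$subset_size == sizes[i + 1]]
        lo <- lo[is.finite(lo)]
        hi <- hi[is.finite(hi)]
        tt <- if (length(lo) < 2 || length(hi) < 2) {
          NULL
        } else if (sd(lo) == 0 && sd(hi) == 0) {
          # Both distributions degenerate: identical means are indistinguishable.
          eq <- isTRUE(all.equal(mean(lo), mean(hi)))
          list(statistic = if (eq) 0 else sign(mean(hi) - mean(lo)) * Inf,
               parameter = NA_real_, p.value = if (eq) 1 else 0)
        } else {
          tryCatch(t.test(hi, lo, var.equal = FALSE), error = function(e) NULL)
        }
        tibble(
          metric = metric, size_low = sizes[i], size_high = sizes[i + 1],
          mean_low = mean(lo, na.rm = TRUE), mean_high = mean(hi, na.rm = TRUE),
          t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
          df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
          p_value = if (is.null(tt)) NA_real_ else tt$p.value
        )
      }) |>
      list_rbind()
  } else {
    tibble(metric = character(), size_low = integer(), size_high = integer(),
           mean_low = double(), mean_high = double(), t = double(),
           df = double(), p_value = double())
  }

  locus_estimable <- as_tibble(est_count, rownames = "subset_size") |>
    pivot_longer(-"subset_size", names_to = "locus_id",
                 values_to = "n_estimable") |>
    mutate(subset_size = as.integer(.data$subset_size), n_iter = n_iter)

  structure(
    list(results = results, comparisons = comparisons,
         locus_estimable = locus_estimable),
    class = "subset_result"
  )
}

#' @export
print.subset_result <- function(x, ...) {
  cat("Reference-subset resampling over sizes",
      paste(sort(unique(x$results$subset_size)), collapse = ", "), "\n")
  print(
    x$results |>
      group_by(.data$subset_size) |>
      summarise(across(c("prop_estimable", "mean_adjusted_R2", "mean_abs_diff"),
                       median), .groups = "drop")
  )
  invisible(x)
}

#' Compare genotype calls from a re-clustered subset pipeline to a full panel
#'
#' When the whole pipeline (clustering, calling, QC) is rerun using only a
#' small subset of reference individuals, cluster positions may be placed
#' incorrectly — most visibly in duplicated-genome locus classes, where a
#' whole cluster can be mislabelled and nearly every genotype at the locus
#' flips. This function compares the two call sets over their shared samples
#' and reports, per locus, the fraction of shared non-missing genotype pairs
#' that disagree, flagging loci that mismatch at more than 95% of genotypes.
#'
#' @param subset_calls,full_calls Genotype-call tibbles (`sample_id`,
#'   `locus_id`, `genotype`).
#' @param high_mismatch Fraction above which a locus is flagged (default
#'   0.95, strict).
#' @return Tibble, one row per locus with at least one shared non-missing
#'   pair: `locus_id`, `n_pairs`, `n_mismatch`, `mismatch_fraction`,
#'   `any_mismatch`, `high_mismatch`. Loci present in only one call set (or
#'   with no comparable pair) are listed in the `"excluded_loci"` attribute.
#' @export
subset_recluster_compare <- function(subset_calls, full_calls,
                                     high_mismatch = 0.95) {
  shared <- intersect(unique(subset_calls$sample_id),
                      unique(full_calls$sample_id))
  if (length(shared) == 0) abort("The two call sets share no samples.")
  pairs <- subset_calls |>
    filter(.data$sample_id %in% shared) |>
    inner_join(full_calls |> filter(.data$sample_id %in% shared),
               by = c("sample_id", "locus_id"), suffix = c("_subset", "_full")) |>
    filter(.data$genotype_subset %in% GENOTYPES,
           .data$genotype_full %in% GENOTYPES)
  out <- pairs |>
    group_by(.data$locus_id) |>
    summarise(
      n_pairs = n(),
      n_mismatch = sum(.data$genotype_subset != .data$genotype_full),
      .groups = "drop"
    ) |>
    mutate(
      mismatch_fraction = .data$n_mismatch / .data$n_pairs,
      any_mismatch = .data$n_mismatch > 0,
      high_mismatch = .data$mismatch_fraction > high_mismatch
    )
  all_loci <- union(unique(subset_calls$locus_id), unique(full_calls$locus_id))
  attr(out, "excluded_loci") <- setdiff(all_loci, out$locus_id)
  out
}
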