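#' Raw per-sample call rates of an intensity or call table
#'
#' For intensity records the raw call rate is the fraction of records with a
#' non-missing theta; for genotype calls it is the fraction not `NOCALL`.
#'
#' @param records Tibble with `sample_id` and either `theta` or `genotype`.
#' @return Tibble `sample_id`, `n_loci`, `n_called`, `call_rate`.
#' @export
sample_call_rates <- function(records) {
  if (nrow(records) == 0) abort("`records` is empty.")
  called <- if ("theta" %in% names(records)) {
    !is.na(records$theta)
  } else if ("genotype" %in% names(records)) {
    !is.na(records$genotype) & records$genotype != "NOCALL"
  } else {
    abort("`records` needs a `theta` or `genotype` column.")
  }
  records |>
    mutate(.called = called) |>
    group_by(.data$sample_id) |>
    summarise(n_loci = n(), n_called = sum(.data$.called),
              call_rate = mean(.data$.called), .groups = "drop")
}

#' Flag samples whose raw call rate is below a threshold
#'
#' Samples are screened on their raw (pre-quality-control) call rate before
#' any clustering is performed; only retained samples should feed the cluster
#' fit. Typical thresholds are 0.90 for a small repeatability design and 0.95
#' for a large pooling design.
#'
#' @param records Intensity records (`sample_id`, `locus_id`, `theta`).
#' @param threshold Minimum raw call rate in \[0, 1\]; samples at or above it
#'   are retained.
#' @return Tibble `sample_id`, `call_rate`, `retained`.
#' @export
exclude_low_callrate_samples <- function(records, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  sample_call_rates(records) |>
    mutate(retained = .data$call_rate >= threshold) |>
    select("sample_id", "call_rate", "retained")
}

#' Clustering configuration for the genotype-calling surrogate
#'
#' @param anchors_snp,anchors_msv3 Expected cluster positions used to label
#'   fitted mixture components as AA/AB/BB for diploid SNP loci and for
#'   MSV-3 loci (whose theta span is compressed to about half).
#' @param min_cluster_n Minimum occupancy for a class mean to be considered
#'   defined (a one-point cluster gives no dispersion estimate).
#' @param sd_floor Lower bound on cluster standard deviations used in scores,
#'   so zero-dispersion clusters still score.
#' @param gentrain_scale Scale of the separation-to-score squash.
#' @param gentrain_degenerate GenTrain-like score reported when fewer than two
#'   clusters are defined (no separation is measurable).
#' @return Named list.
#' @export
cluster_config <- function(anchors_snp = c(0.05, 0.50, 0.95),
                           anchors_msv3 = c(0.05, 0.275, 0.50),
                           min_cluster_n = 2, sd_floor = 1e-6,
                           gentrain_scale = 4, gentrain_degenerate = 0) {
  as.list(environment())
}

# Order-preserving assignment of k ordered component means to the 3 genotype
# slots, minimising total distance to the anchor positions.
assign_components <- function(means, anchors) {
  k <- length(means)
  slots <- utils::combn(3, k)
  cost <- apply(slots, 2, function(s) sum(abs(means - anchors[s])))
  slots[, which.min(cost)]
}

#' Fit genotype clusters in theta for one locus
#'
#' A surrogate for proprietary array-clustering software: fits a 1- to
#' 3-component univariate Gaussian mixture to the non-missing theta values
#' (model selection by BIC), labels the ordered components as AA/AB/BB by
#' proximity to anchor positions, and summarises cluster separation as a
#' GenTrain-like score in \[0, 1\]
#' (`1 - exp(-sep / gentrain_scale)` where `sep` is the minimum adjacent
#' `|mean difference| / pooled sd`). Inputs with at most three distinct theta
#' values are clustered directly on those values.
#'
#' @param thetas Numeric vector of theta values; `NA` ignored.
#' @param anchors Length-3 anchor thetas for labelling.
#' @param config See [cluster_config()].
#' @return One-row tibble: `mean_AA`, `mean_AB`, `mean_BB`, `sd_AA`, `sd_AB`,
#'   `sd_BB`, `n_AA`, `n_AB`, `n_BB`, `n_obs`, `n_clusters`,
#'   `gentrain_score`, `unclusterable`. Undefined class means are `NA`.
#' @export
cluster_locus <- function(thetas, anchors = NULL, config = cluster_config()) {
  anchors <- anchors %||% config$anchors_snp
  x <- thetas[!is.na(thetas)]
  empty <- tibble(
    mean_AA = NA_real_, mean_AB = NA_real_, mean_BB = NA_real_,
    sd_AA = NA_real_, sd_AB = NA_real_, sd_BB = NA_real_,
    n_AA = NA_integer_, n_AB = NA_integer_, n_BB = NA_integer_,
    n_obs = length(x), n_clusters = 0L,
    gentrain_score = NA_real_, unclusterable = TRUE
  )
  if (length(x) < 2) return(empty)

  ux <- sort(unique(x))
  if (length(ux) <= 3) {
    comp <- match(x, ux)
    means <- ux
  } else {
    fit <- tryCatch(
      Mclust(x, G = 1:3, modelNames = c("E", "V"), verbose = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit)) return(empty)
    ord <- order(fit$parameters$mean)
    means <- fit$parameters$mean[ord]
    comp <- match(fit$classification, ord)
  }
  k <- length(means)
  sds <- vapply(seq_len(k), function(j) {
    xs <- x[comp == j]
    if (length(xs) > 1) sd(xs) else 0
  }, numeric(1))
  ns <- tabulate(comp, nbins = k)

  # Drop under-occupied components: their means are not considered defined.
  keep <- ns >= config$min_cluster_n
  if (!any(keep)) return(empty)
  means <- means[keep]; sds <- sds[keep]; ns <- ns[keep]
  slots <- assign_components(means, anchors)

  out_mean <- out_sd <- rep(NA_real_, 3)
  out_n <- rep(NA_integer_, 3)
  out_mean[slots] <- means
  out_sd[slots] <- sds
  out_n[slots] <- as.integer(ns)

  if (length(means) >= 2) {
    pooled <- sqrt((sds[-length(sds)]^2 + sds[-1]^2) / 2)
    sep <- min(diff(means) / pmax(pooled, config$sd_floor))
    gentrain <- 1 - exp(-sep / config$gentrain_scale)
  } else {
    gentrain <- config$gentrain_degenerate
  }

  tibble(
    mean_AA = out_mean[1], mean_AB = out_mean[2], mean_BB = out_mean[3],
    sd_AA = out_sd[1], sd_AB = out_sd[2], sd_BB = out_sd[3],
    n_AA = out_n[1], n_AB = out_n[2], n_BB = out_n[3],
    n_obs = length(x), n_clusters = length(means),
    gentrain_score = gentrain, unclusterable = FALSE
  )
}

#' Fit genotype clusters for every locus of an intensity table
#'
#' @param records Intensity records (`sample_id`, `locus_id`, `theta`).
#'   Restrict to call-rate-retained samples before calling this.
#' @param panel Optional locus panel; when given, MSV-3 loci are labelled
#'   against the compressed MSV-3 anchors.
#' @param config See [cluster_config()].
#' @return Cluster-model tibble, one row per locus (`locus_id` + the columns
#'   of [cluster_locus()]).
#' @export
cluster_loci <- function(records, panel = NULL, config = cluster_config()) {
  msv3 <- if (!is.null(panel)) {
    panel$locus_id[panel$classification == "MSV3"]
  } else character(0)
  records |>
    group_by(.data$locus_id) |>
    group_modify(function(d, key) {
      anchors <- if (key$locus_id %in% msv3) config$anchors_msv3 else
        config$anchors_snp
      cluster_locus(d$theta, anchors, config)
    }) |>
    ungroup()
}

#' Cluster models from known genotype truth
#'
#' The oracle counterpart of [cluster_loci()] for synthetic data: per locus,
#' cluster means/dispersions are the sample statistics of theta grouped by the
#' simulated true genotype. Useful for large-scale experiments where fitting
#' a mixture per locus is unnecessary, and as reference cluster positions in
#' resampling studies.
#'
#' @param records Intensity records with `sample_id`.
#' @param truth Genotype truth (`individual_id`, `locus_id`, `genotype`) —
#'   joined on `sample_id == individual_id` unless `records` carries
#'   `individual_id`.
#' @param samples Optional sample sheet mapping `sample_id` to
#'   `individual_id`.
#' @param min_cluster_n Minimum class occupancy for a defined mean.
#' @param config See [cluster_config()] (for the GenTrain-like score).
#' @return Cluster-model tibble as in [cluster_loci()].
#' @export
cluster_from_truth <- function(records, truth, samples = NULL,
                               min_cluster_n = 2, config = cluster_config()) {
  recs <- records
  if (!"individual_id" %in% names(recs)) {
    if (!is.null(samples)) {
      recs <- left_join(recs, select(samples, "sample_id", "individual_id"),
                        by = "sample_id")
    } else {
      recs <- mutate(recs, individual_id = .data$sample_id)
    }
  }
  recs <- recs |>
    inner_join(truth |> select("individual_id", "locus_id", "genotype"),
               by = c("individual_id", "locus_id")) |>
    filter(!is.na(.data$theta))

  stats <- recs |>
    group_by(.data$locus_id, .data$genotype) |>
    summarise(m = mean(.data$theta),
              s = if (n() > 1) sd(.data$theta) else 0,
              nn = n(), .groups = "drop") |>
    filter(.data$nn >= min_cluster_n)

  wide <- stats |>
    pivot_wider(names_from = "genotype",
                values_from = c("m", "s", "nn"),
                names_sep = "_")
  for (g in GENOTYPES) {
    for (p in c("m", "s", "nn")) {
      col <- paste(p, g, sep = "_")
      if (!col %in% names(wide)) wide[[col]] <- if (p == "nn") NA_integer_ else NA_real_
    }
  }
  out <- wide |>
    transmute(
      .data$locus_id,
      mean_AA = .data$m_AA, mean_AB = .data$m_AB, mean_BB = .data$m_BB,
      sd_AA = .data$s_AA, sd_AB = .data$s_AB, sd_BB = .data$s_BB,
      n_AA = as.integer(.data$nn_AA), n_AB = as.integer(.data$nn_AB),
      n_BB = as.integer(.data$nn_BB)
    )
  out |>
    mutate(
      n_obs = rowSums(cbind(.data$n_AA, .data$n_AB, .data$n_BB), na.rm = TRUE),
      n_clusters = rowSums(!is.na(cbind(.data$mean_AA, .data$mean_AB,
                                        .data$mean_BB))),
      gentrain_score = gentrain_from_model(.data$mean_AA, .data$mean_AB,
                                           .data$mean_BB, .data$sd_AA,
                                           .data$sd_AB, .data$sd_BB, config),
      unclusterable = .data$n_clusters == 0
    )
}

# Vectorised GenTrain-like score from wide model columns.
gentrain_from_model <- function(mAA, mAB, mBB, sAA, sAB, sBB,
                                config = cluster_config()) {
  sep_pair <- function(m1, m2, s1, s2) {
    (m2 - m1) / pmax(sqrt((s1^2 + s2^2) / 2), config$sd_floor)
  }
  s1 <- sep_pair(mAA, mAB, sAA, sAB)
  s2 <- sep_pair(mAB, mBB, sAB, sBB)
  s3 <- sep_pair(mAA, mBB, sAA, sBB) # used when AB is absent
  sep <- pmin(s1, s2, na.rm = TRUE)
  sep <- ifelse(is.na(sep), s3, sep)
  ifelse(is.na(sep), config$gentrain_degenerate,
         1 - exp(-sep / config$gentrain_scale))
}

#' Call genotypes against fitted cluster models
#'
#' Assigns each record to the nearest defined cluster in standardised
#' distance (`z = |theta - mean| / max(sd, sd_floor)`), with ties broken
#' toward the lower-theta genotype, and computes a GenCall-like confidence
#' score `exp(-z1^2 / 2) * z2 / (z1 + z2)`, where `z1` is the standardised
#' distance to the assigned cluster and `z2` to the nearest competing
#' cluster (the margin factor is 1 when no competitor exists). The score is 1
#' at a cluster centre with a distant competitor and decreases with distance
#' from the assigned centre. Records with missing theta, or with a score
#' below `call_threshold`, are `NOCALL`.
#'
#' @param records Intensity records (`sample_id`, `locus_id`, `theta`).
#' @param models Cluster-model tibble ([cluster_loci()] or
#'   [cluster_from_truth()]).
#' @param call_threshold Minimum confidence score for a call (e.g. 0.15 for a
#'   small stringent design, 0.05 for a large pooling design).
#' @param config See [cluster_config()].
#' @return Tibble `sample_id`, `locus_id`, `genotype` (`"AA"`, `"AB"`,
#'   `"BB"`, `"NOCALL"`), `gencall_score`.
#' @export
call_genotypes <- function(records, models, call_threshold = 0.05,
                           config = cluster_config()) {
  stopifnot(call_threshold >= 0, call_threshold <= 1)
  d <- records |>
    select("sample_id", "locus_id", "theta") |>
    inner_join(
      models |> select("locus_id", "mean_AA", "mean_AB", "mean_BB",
                       "sd_AA", "sd_AB", "sd_BB"),
      by = "locus_id"
    )
  z <- cbind(
    abs(d$theta - d$mean_AA) / pmax(d$sd_AA, config$sd_floor),
    abs(d$theta - d$mean_AB) / pmax(d$sd_AB, config$sd_floor),
    abs(d$theta - d$mean_BB) / pmax(d$sd_BB, config$sd_floor)
  )
  z[is.na(z)] <- Inf
  # Nearest cluster; ties go to the first (lowest-theta) genotype.
  assigned <- max.col(-z, ties.method = "first")
  z1 <- z[cbind(seq_len(nrow(z)), assigned)]
  z[cbind(seq_len(nrow(z)), assigned)] <- Inf
  z2 <- do.call(pmin, as.data.frame(z))

  margin <- ifelse(is.finite(z2),
                   ifelse(z1 + z2 > 0, z2 / (z1 + z2), 0.5),
                   1)
  score <- exp(-z1^2 / 2) * margin
  score[!is.finite(z1)] <- 0 # missing theta or no defined cluster

  genotype <- GENOTYPES[assigned]
  nocall <- !is.finite(z1) | score < call_threshold
  genotype[nocall] <- "NOCALL"

  tibble(
    sample_id = d$sample_id,
    locus_id = d$locus_id,
    genotype = genotype,
    gencall_score = score
  )
}

#' Rule-based cluster review flags
#'
#' Automated stand-in for visual inspection of cluster plots: flags loci whose
#' adjacent defined clusters overlap (standardised separation below
#' `min_separation`) and loci that could not be clustered at all. Absent
#' genotype classes are recorded but do not flag a locus on their own (a
#' monomorphic locus legitimately shows one cluster).
#'
#' @param models Cluster-model tibble.
#' @param min_separation Minimum adjacent `|mean difference| / pooled sd`.
#' @param config See [cluster_config()].
#' @return Tibble `locus_id`, `separation`, `n_clusters`, `absent_classes`,
#'   `flagged`, `flag_reason`.
#' @export
cluster_flags <- function(models, min_separation = 2,
                          config = cluster_config()) {
  sep_pair <- function(m1, m2, s1, s2) {
    (m2 - m1) / pmax(sqrt((s1^2 + s2^2) / 2), config$sd_floor)
  }
  models |>
    mutate(
      separation = pmin(
        sep_pair(.data$mean_AA, .data$mean_AB, .data$sd_AA, .data$sd_AB),
        sep_pair(.data$mean_AB, .data$mean_BB, .data$sd_AB, .data$sd_BB),
        sep_pair(.data$mean_AA, .data$mean_BB, .data$sd_AA, .data$sd_BB),
        na.rm = TRUE
      ),
      absent_classes = 3L - .data$n_clusters,
      flag_reason = case_when(
        .data$unclusterable ~ "unclusterable",
        !is.na(.data$separation) & .data$separation < min_separation ~ "overlap",
        TRUE ~ NA_character_
      ),
      flagged = !is.na(.data$flag_reason)
    ) |>
    select("locus_id", "separation", "n_clusters", "absent_classes",
           "flagged", "flag_reason")
}
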