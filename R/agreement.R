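# Adjusted R-squared of the simple linear regression y ~ x,
# 1 - (1 - R^2) (n - 1) / (n - 2); NA when n < 3 or x or y is constant.
adj_r2 <- function(x, y) {
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  r2 <- cor(x, y)^2
  1 - (1 - r2) * (n - 1) / (n - 2)
}

#' Agreement between empirical and estimated pool allele frequencies
#'
#' For each pool, regresses the estimated (allelotyped) frequency on the
#' empirical frequency (allele counting over individually genotyped members)
#' by simple linear regression and reports the adjusted R-squared
#' `1 - (1 - R^2) (n - 1) / (n - 2)`, together with the mean per-locus
#' absolute difference between the two values (the maximum of the pair minus
#' the minimum) and its standard error.
#'
#' @param df Tibble with columns `pool_id`, `empirical`, `estimated`; rows
#'   with a missing value in either are dropped per pool.
#' @return Tibble, one row per pool: `pool_id`, `n_loci`, `adjusted_R2`,
#'   `mean_abs_diff`, `se_abs_diff`. Pools with fewer than 3 complete pairs
#'   get `NA` statistics with a warning.
#' @export
agreement <- function(df) {
  stopifnot(all(c("pool_id", "empirical", "estimated") %in% names(df)))
  out <- df |>
    filter(!is.na(.data$empirical), !is.na(.data$estimated)) |>
    group_by(.data$pool_id) |>
    summarise(
      n_loci = n(),
      adjusted_R2 = adj_r2(.data$empirical, .data$estimated),
      mean_abs_diff = mean(abs(.data$estimated - .data$empirical)),
      se_abs_diff = sd(abs(.data$estimated - .data$empirical)) / sqrt(n()),
      .groups = "drop"
    )
  if (any(is.na(out$adjusted_R2))) {
    warn("Some pools have fewer than 3 complete pairs; adjusted R2 is NA there.")
  }
  out
}

#' Model the drivers of allele-frequency estimation error
#'
#' Fits an ordinary least-squares model of the per-locus absolute difference
#' between empirical and estimated frequencies on minor allele frequency, the
#' per-locus clustering-quality (GenTrain-like) score, and locus
#' classification (with `SNP` as the reference level). Larger MAF and poorer
#' clustering are expected to increase the error; compressed-span locus
#' classes typically show class effects.
#'
#' @param df Tibble with columns `abs_diff`, `maf`, `gentrain_score`,
#'   `classification`.
#' @return Object of class `error_driver_fit` wrapping the `lm` fit; use
#'   [generics::tidy()] for the coefficient table (estimate, SE, t, p) and
#'   [generics::glance()] for fit statistics.
#' @export
error_driver_glm <- function(df) {
  need <- c("abs_diff", "maf", "gentrain_score", "classification")
  stopifnot(all(need %in% names(df)))
  df <- df |> filter(complete.cases(df[, need]))
  lv <- unique(as.character(df$classification))
  form <- if (length(lv) < 2) {
    warn("Only one classification level present; fitting without class terms.")
    abs_diff ~ maf + gentrain_score
  } else {
    ref <- if ("SNP" %in% lv) "SNP" else lv[1]
    df$classification <- stats::relevel(factor(df$classification), ref = ref)
    abs_diff ~ maf + gentrain_score + classification
  }
  fit <- lm(form, data = df)
  if (any(is.na(coef(fit)))) {
    abort(paste0(
      "Collinear design: coefficient(s) not estimable: ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
    ))
  }
  structure(list(fit = fit, n = nrow(df), levels = lv),
            class = "error_driver_fit")
}

#' @export
print.error_driver_fit <- function(x, ...) {
  cat("Error-driver linear model (", x$n, " loci)\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @export
tidy.error_driver_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @export
glance.error_driver_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = x$n
  )
}

#' Assemble the per-locus error table behind [error_driver_glm()]
#'
#' Joins pool-mean estimates to empirical frequencies, averages the absolute
#' difference per locus over pools, and attaches MAF and clustering-quality
#' covariates from a QC report and cluster models.
#'
#' @param pool_means Output of [summarise_pool()].
#' @param empirical Output of [empirical_freqs()].
#' @param qc Output of [qc_report()] (for `classification` and `maf`).
#' @param models Cluster-model tibble (for `gentrain_score`).
#' @return Tibble `locus_id`, `abs_diff`, `maf`, `gentrain_score`,
#'   `classification`.
#' @export
error_table <- function(pool_means, empirical, qc, models) {
  pool_means |>
    inner_join(empirical, by = c("pool_id", "locus_id")) |>
    filter(!is.na(.data$freq_B), !is.na(.data$empirical)) |>
    group_by(.data$locus_id) |>
    summarise(abs_diff = mean(abs(.data$freq_B - .data$empirical)),
              .groups = "drop") |>
    inner_join(select(qc, "locus_id", "classification", "maf"),
               by = "locus_id") |>
    inner_join(select(models, "locus_id", "gentrain_score"), by = "locus_id")
}
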