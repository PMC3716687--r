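#' Repeatability of replicated pool frequency estimates
#'
#' Fits a one-way random-effects model (locus as a random intercept, REML via
#' `lme4::lmer`) to replicated frequency estimates and reports repeatability —
#' the intra-class correlation, i.e. the proportion of total variance
#' explained by among-locus variance:
#' `sigma^2_locus / (sigma^2_locus + sigma^2_residual)`.
#' Uncertainty is quantified by parametric bootstrap over refitted models
#' (percentile interval), or skipped with `interval = "none"`.
#'
#' @param df Tibble with a grouping column and a value column.
#' @param value,group Column names (strings) of the estimate and the locus
#'   grouping; defaults `"freq_B"` and `"locus_id"`.
#' @param interval `"boot"` (default) or `"none"`.
#' @param nsim Number of bootstrap refits.
#' @param level Interval coverage.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `repeatability_fit`: a list with `repeatability`,
#'   `interval_low`, `interval_high`, `var_locus`, `var_residual`, `n_groups`,
#'   `n_obs`, `method_label` and the underlying `fit`. `tidy()`/`glance()`
#'   methods are provided.
#' @export
repeatability <- function(df, value = "freq_B", group = "locus_id",
                          interval = c("boot", "none"), nsim = 100,
                          level = 0.95, seed = NULL) {
  interval <- match.arg(interval)
  stopifnot(all(c(value, group) %in% names(df)))
  d <- tibble(y = df[[value]], g = factor(df[[group]])) |>
    filter(!is.na(.data$y))
  reps_per_group <- table(d$g)
  if (sum(reps_per_group >= 2) < 10) {
    abort("Repeatability needs >= 2 replicates per locus for at least 10 loci.")
  }
  if (all(reps_per_group < 2)) abort("No locus has replicated estimates.")

  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | g), data = d, REML = TRUE)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_locus <- vc$vcov[vc$grp == "g"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  r <- var_locus / (var_locus + var_res)

  lo <- hi <- NA_real_
  if (interval == "boot") {
    if (!is.null(seed)) set.seed(seed)
    stat <- function(m) {
      v <- as.data.frame(lme4::VarCorr(m))
      v$vcov[v$grp == "g"] / sum(v$vcov[v$grp %in% c("g", "Residual")])
    }
    bs <- suppressMessages(suppressWarnings(
      lme4::bootMer(fit, stat, nsim = nsim, use.u = FALSE, type = "parametric")
    ))
    qs <- quantile(bs$t, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    lo <- min(qs[1], r)
    hi <- max(qs[2], r)
  }

  structure(
    list(
      repeatability = r, interval_low = lo, interval_high = hi,
      var_locus = var_locus, var_residual = var_res,
      n_groups = nlevels(d$g), n_obs = nrow(d),
      method_label = paste0(
        "REML random-intercept (lme4)",
        if (interval == "boot") sprintf(", %d%% parametric-bootstrap interval (%d sims)",
                                        round(level * 100), nsim)
      ),
      fit = fit
    ),
    class = "repeatability_fit"
  )
}

#' @export
print.repeatability_fit <- function(x, ...) {
  cat(sprintf("Repeatability = %.4f", x$repeatability))
  if (!is.na(x$interval_low)) {
    cat(sprintf(" [%.4f, %.4f]", x$interval_low, x$interval_high))
  }
  cat(sprintf("\n  among-locus variance %.3g, residual variance %.3g (%d loci, %d estimates)\n  %s\n",
              x$var_locus, x$var_residual, x$n_groups, x$n_obs, x$method_label))
  invisible(x)
}

#' @export
tidy.repeatability_fit <- function(x, ...) {
  tibble(
    term = c("repeatability", "var_locus", "var_residual"),
    estimate = c(x$repeatability, x$var_locus, x$var_residual),
    conf.low = c(x$interval_low, NA, NA),
    conf.high = c(x$interval_high, NA, NA)
  )
}

#' @export
glance.repeatability_fit <- function(x, ...) {
  tibble(repeatability = x$repeatability, n_loci = x$n_groups,
         n_obs = x$n_obs, method = x$method_label)
}
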