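#' Plot empirical vs estimated pool allele frequencies
#'
#' One panel per pool, with the identity line and the per-pool adjusted
#' R-squared in the strip label.
#'
#' @param df Tibble with `pool_id`, `empirical`, `estimated`.
#' @return A ggplot object.
#' @export
plot_agreement <- function(df) {
  agr <- agreement(df)
  labs <- setNames(
    sprintf("%s (adj. R² = %.3f)", agr$pool_id, agr$adjusted_R2),
    agr$pool_id
  )
  ggplot2::ggplot(
    df |> filter(!is.na(.data$empirical), !is.na(.data$estimated)),
    ggplot2::aes(x = .data$empirical, y = .data$estimated)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::facet_wrap(~ .data$pool_id,
                        labeller = ggplot2::labeller(pool_id = labs)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Empirical B-allele frequency",
                  y = "Estimated B-allele frequency") +
    ggplot2::theme_bw()
}

#' Boxplots of subset-resampling metrics by subset size
#'
#' @param x A `subset_result` (or its `results` tibble).
#' @param ... Unused.
#' @return A ggplot object with one facet per metric.
#' @export
plot_subset_results <- function(x, ...) {
  res <- if (inherits(x, "subset_result")) x$results else x
  long <- res |>
    pivot_longer(c("prop_estimable", "mean_adjusted_R2", "mean_abs_diff"),
                 names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric,
                           levels = c("prop_estimable", "mean_adjusted_R2",
                                      "mean_abs_diff"),
                           labels = c("Proportion estimable",
                                      "Mean adjusted R²",
                                      "Mean absolute difference")))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$subset_size),
                                     y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "Reference individuals sampled", y = NULL) +
    ggplot2::theme_bw()
}

#' @export
autoplot.subset_result <- function(object, ...) plot_subset_results(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the theta distribution and fitted clusters of one locus
#'
#' @param records Intensity records for the locus (or with `locus_id` to
#'   filter by `locus`).
#' @param model One-row cluster-model tibble for the locus (optional; cluster
#'   means drawn as dashed verticals).
#' @param locus Locus id to filter on when `records` spans several loci.
#' @return A ggplot object.
#' @export
plot_cluster <- function(records, model = NULL, locus = NULL) {
  if (!is.null(locus)) {
    records <- filter(records, .data$locus_id == locus)
    if (!is.null(model) && "locus_id" %in% names(model)) {
      model <- filter(model, .data$locus_id == locus)
    }
  }
  p <- ggplot2::ggplot(filter(records, !is.na(.data$theta)),
                       ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_histogram(bins = 60, boundary = 0) +
    ggplot2::xlim(-0.02, 1.02) +
    ggplot2::labs(x = "Theta", y = "Samples") +
    ggplot2::theme_bw()
  if (!is.null(model) && nrow(model) == 1) {
    means <- c(model$mean_AA, model$mean_AB, model$mean_BB)
    means <- means[!is.na(means)]
    p <- p + ggplot2::geom_vline(xintercept = means, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot fragment-size proportion above 1000 bp against cohort year
#'
#' @param samples Sample sheet with `cohort_year` and `prop_gt1000`.
#' @return A ggplot object.
#' @export
plot_fragment_profiles <- function(samples) {
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$cohort_year,
                                        y = .data$prop_gt1000)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Cohort year", y = "Proportion of DNA > 1000 bp") +
    ggplot2::theme_bw()
}
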