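#' Pairwise Spearman rank correlations
#'
#' Computes Spearman's rho with average-rank tie handling and an asymptotic
#' (t-approximation) p-value for every pair of the requested numeric columns,
#' over pairwise-complete observations. Pairs where either vector is constant
#' get `NA` rho with a note in `status`.
#'
#' @param df A data frame.
#' @param vars Character vector of column names; default all numeric columns.
#' @return Tibble `var1`, `var2`, `n`, `rho`, `p_value`, `status`.
#' @export
rank_correlations <- function(df, vars = NULL) {
  vars <- vars %||% names(df)[vapply(df, is.numeric, logical(1))]
  stopifnot(length(vars) >= 2, all(vars %in% names(df)))
  pairs <- utils::combn(vars, 2)
  purrr::map(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    x <- df[[v1]]; y <- df[[v2]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4) {
      return(tibble(var1 = v1, var2 = v2, n = length(x), rho = NA_real_,
                    p_value = NA_real_, status = "too_few_observations"))
    }
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(var1 = v1, var2 = v2, n = length(x), rho = NA_real_,
                    p_value = NA_real_, status = "constant_vector"))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tibble(var1 = v1, var2 = v2, n = length(x),
           rho = unname(ct$estimate), p_value = ct$p.value, status = "ok")
  }) |>
    list_rbind()
}
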