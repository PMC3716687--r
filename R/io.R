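#' Read a "final report"-style genotype/intensity table
#'
#' Reads the tab-separated export format with header columns `Sample ID`,
#' `SNP Name`, `GC Score`, `Theta`, `R`. Extra columns are ignored (with a
#' message); `NaN` or empty cells become missing. Theta must lie in \[0, 1\];
#' a record missing exactly one of theta/R is coerced to fully missing with a
#' warning, since a dropout loses both channels.
#'
#' @param path File path.
#' @return Tibble `sample_id`, `locus_id`, `gc_score`, `theta`,
#'   `r_intensity`.
#' @export
read_final_report <- function(path) {
  d <- readr::read_tsv(path, na = c("", "NA", "NaN"), show_col_types = FALSE,
                       progress = FALSE)
  required <- c("Sample ID", "SNP Name", "GC Score", "Theta", "R")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    abort(paste0("Final report is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(d), required)
  if (length(extra) > 0) {
    inform(paste0("Ignoring extra column(s): ", paste(extra, collapse = ", ")))
  }
  out <- tibble(
    sample_id = as.character(d[["Sample ID"]]),
    locus_id = as.character(d[["SNP Name"]]),
    gc_score = as.numeric(d[["GC Score"]]),
    theta = as.numeric(d[["Theta"]]),
    r_intensity = as.numeric(d[["R"]])
  )
  if (any(out$theta < 0 | out$theta > 1, na.rm = TRUE)) {
    abort("Theta values outside [0, 1] found in final report.")
  }
  half <- xor(is.na(out$theta), is.na(out$r_intensity))
  if (any(half)) {
    warn(sprintf("%d record(s) had exactly one of Theta/R missing; set both missing.",
                 sum(half)))
    out$theta[half] <- NA_real_
    out$r_intensity[half] <- NA_real_
  }
  out
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NaN", formatC(x, digits = digits, format = "f"))
}

#' Write intensity records as a final report
#'
#' @param records Tibble with `sample_id`, `locus_id`, `theta`,
#'   `r_intensity` and optionally `gc_score`. Floats are serialised at 6
#'   decimals; missing values as `NaN`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_final_report <- function(records, path) {
  gc <- if ("gc_score" %in% names(records)) records$gc_score else
    rep(NA_real_, nrow(records))
  out <- tibble(
    `Sample ID` = records$sample_id,
    `SNP Name` = records$locus_id,
    `GC Score` = fmt_num(gc, 4),
    Theta = fmt_num(records$theta),
    R = fmt_num(records$r_intensity)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write tab-separated pipeline tables
#'
#' Thin TSV helpers for the locus manifest (`locus_id`, `classification`,
#' `design_score`), sample sheet, pool sheet (`pool_id`, `individual_id`)
#' and any intermediate table. Missing values are written as `NaN`.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @return Read: a tibble. Write: `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  readr::write_tsv(df, path, na = "NaN", progress = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, na = c("", "NA", "NaN"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Pipeline run configuration
#'
#' Bundles thresholds, simulation scale and resampling settings, with two
#' preset profiles: `"dataset1"` (small temporal repeatability design: raw
#' sample call rate 0.90, call confidence threshold 0.15) and `"dataset2"`
#' (large pooling design: 0.95 and 0.05). All thresholds are validated to
#' \[0, 1\] before any stage runs.
#'
#' @param profile `"dataset2"` (default), `"dataset1"` or `"custom"`.
#' @param ... Overrides of the defaults listed below.
#' @return List of class `run_config` with elements `profile`,
#'   `raw_callrate_threshold`, `call_threshold`, `locus_callrate`,
#'   `het_threshold`, `maf_threshold`, `n_snp`, `n_msv3`, `n_mono`,
#'   `n_discard`, `n_individuals`, `pool_sizes`, `noise_sd`, `subset_sizes`,
#'   `subset_iterations`, `clustering` (`"mixture"` or `"truth"`), `seed`.
#' @export
run_config <- function(profile = c("dataset2", "dataset1", "custom"), ...) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    raw_callrate_threshold = if (profile == "dataset1") 0.90 else 0.95,
    call_threshold = if (profile == "dataset1") 0.15 else 0.05,
    locus_callrate = 0.95,
    het_threshold = 0.1,
    maf_threshold = 0.05,
    n_snp = 140, n_msv3 = 30, n_mono = 20, n_discard = 10,
    n_individuals = 100, pool_sizes = c(40, 60),
    noise_sd = 0.01,
    subset_sizes = c(10, 20), subset_iterations = 10,
    clustering = "mixture",
    seed = 1L
  )
  cfg <- modifyList(base, list(...))
  thr <- c("raw_callrate_threshold", "call_threshold", "locus_callrate",
           "het_threshold", "maf_threshold")
  for (t in thr) {
    if (!is.numeric(cfg[[t]]) || cfg[[t]] < 0 || cfg[[t]] > 1) {
      abort(sprintf("Configuration error: `%s` must be in [0, 1].", t))
    }
  }
  if (!cfg$clustering %in% c("mixture", "truth")) {
    abort("Configuration error: `clustering` must be \"mixture\" or \"truth\".")
  }
  # Every pooled individual is also an individually genotyped reference.
  cfg$n_individuals <- sum(cfg$pool_sizes)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with a `profile` key and any [run_config()] fields.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "dataset2"
  y$profile <- NULL
  do.call(run_config, c(list(profile = profile), y))
}

#' Run the full synthetic allelotyping pipeline
#'
#' Executes simulate -> call -> qc -> allelotype -> evaluate on synthetic
#' data at the configured scale, writing every intermediate table as TSV, a
#' machine-readable `summary.json` (with the config hash and seed) and a
#' plain-text log to `outdir`. Re-running with the same config and seed
#' reproduces the outputs.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(...)),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  cfg_hash <- rlang::hash(unclass(config))
  seed <- as.integer(config$seed)
  logf("pipeline start: profile=%s seed=%d config_hash=%s R=%s",
       config$profile, seed, cfg_hash, as.character(getRversion()))

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    panel <- simulate_panel(config$n_snp, config$n_msv3, config$n_mono,
                            config$n_discard, seed = seed)
    design <- dataset2_design(pool_sizes = config$pool_sizes, seed = seed + 1L)
    ind <- simulate_individuals(panel, design$samples, seed = seed + 2L)
    pool_recs <- simulate_pool_intensity(design$pools, design$pool_members,
                                         ind$truth, panel,
                                         noise_sd = config$noise_sd,
                                         seed = seed + 3L)
    list(panel = panel, design = design, ind = ind, pool_recs = pool_recs)
  })
  write_tsv_table(sim$panel |> select("locus_id", "classification", "design_score"),
                  file.path(outdir, "locus_manifest.tsv"))
  write_tsv_table(sim$design$samples, file.path(outdir, "sample_sheet.tsv"))
  write_tsv_table(sim$design$pool_members, file.path(outdir, "pool_sheet.tsv"))
  write_final_report(sim$ind$intensities,
                     file.path(outdir, "individual_final_report.tsv"))
  logf("simulate: %d loci, %d individuals, %d pool records",
       nrow(sim$panel), nrow(sim$design$samples), nrow(sim$pool_recs))

  # --- call -------------------------------------------------------------
  calls_all <- stage("call", {
    retained <- exclude_low_callrate_samples(sim$ind$intensities,
                                             config$raw_callrate_threshold)
    kept <- retained$sample_id[retained$retained]
    recs <- sim$ind$intensities |> filter(.data$sample_id %in% kept)
    analysable <- filter_by_classification(sim$panel)
    recs <- recs |> filter(.data$locus_id %in% analysable$locus_id)
    models <- if (config$clustering == "truth") {
      cluster_from_truth(recs, sim$ind$truth)
    } else {
      cluster_loci(recs, panel = sim$panel)
    }
    calls <- call_genotypes(recs, models, config$call_threshold)
    list(models = models, calls = calls, retained = retained)
  })
  write_tsv_table(calls_all$models, file.path(outdir, "cluster_models.tsv"))
  write_tsv_table(calls_all$calls, file.path(outdir, "genotype_calls.tsv"))
  logf("call: %d samples retained, %d loci clustered",
       sum(calls_all$retained$retained), nrow(calls_all$models))

  # --- qc ---------------------------------------------------------------
  qc <- stage("qc", {
    qc_report(calls_all$calls, sim$panel, models = calls_all$models,
              locus_callrate = config$locus_callrate,
              het_threshold = config$het_threshold)
  })
  write_tsv_table(
    qc |> mutate(fail_reasons = map_chr(.data$fail_reasons, paste, collapse = ";")),
    file.path(outdir, "qc_report.tsv")
  )
  valid_loci <- qc$locus_id[qc$passed]
  poly <- polymorphic_set(
    calls_all$calls |> filter(.data$locus_id %in% valid_loci),
    config$maf_threshold
  )
  logf("qc: %d/%d loci passed, %d polymorphic", length(valid_loci), nrow(qc),
       length(poly))

  # --- allelotype -------------------------------------------------------
  al <- stage("allelotype", {
    pool_recs <- sim$pool_recs |> filter(.data$locus_id %in% valid_loci)
    estimates <- allelotype(pool_recs, calls_all$models)
    pool_means <- summarise_pool(estimates)
    emp <- empirical_freqs(calls_all$calls |>
                             filter(.data$locus_id %in% valid_loci),
                           sim$design$pool_members)
    list(estimates = estimates, pool_means = pool_means, emp = emp)
  })
  write_tsv_table(al$estimates, file.path(outdir, "estimates.tsv"))
  write_tsv_table(al$pool_means, file.path(outdir, "pool_means.tsv"))
  write_tsv_table(al$emp, file.path(outdir, "empirical_freqs.tsv"))

  # --- evaluate ---------------------------------------------------------
  ev <- stage("evaluate", {
    agr <- agreement(
      al$pool_means |>
        inner_join(al$emp, by = c("pool_id", "locus_id")) |>
        transmute(.data$pool_id, empirical = .data$empirical,
                  estimated = .data$freq_B)
    )
    rep_fit <- tryCatch(
      repeatability(al$estimates |> filter(!is.na(.data$freq_B)),
                    interval = "none"),
      error = function(e) NULL
    )
    et <- error_table(al$pool_means, al$emp, qc, calls_all$models)
    glm_fit <- if (length(unique(et$classification)) >= 1 && nrow(et) >= 10) {
      tryCatch(error_driver_glm(et), error = function(e) NULL,
               warning = function(w) suppressWarnings(error_driver_glm(et)))
    } else NULL
    subs <- subset_resampling(
      ref = calls_all$calls |>
        inner_join(sim$ind$intensities, by = c("sample_id", "locus_id")) |>
        filter(.data$locus_id %in% valid_loci),
      pool_records = sim$pool_recs |> filter(.data$locus_id %in% valid_loci),
      empirical = al$emp,
      sizes = config$subset_sizes, n_iter = config$subset_iterations,
      seed = seed + 4L
    )
    list(agr = agr, rep_fit = rep_fit, glm_fit = glm_fit, subs = subs)
  })
  write_tsv_table(ev$agr, file.path(outdir, "agreement.tsv"))
  write_tsv_table(ev$subs$results, file.path(outdir, "subset_results.tsv"))
  write_tsv_table(ev$subs$comparisons, file.path(outdir, "subset_ttests.tsv"))
  if (!is.null(ev$glm_fit)) {
    write_tsv_table(tidy(ev$glm_fit), file.path(outdir, "error_drivers.tsv"))
  }

  summary <- list(
    config_hash = cfg_hash,
    seed = seed,
    profile = config$profile,
    n_loci = nrow(sim$panel),
    n_loci_valid = length(valid_loci),
    n_loci_polymorphic = length(poly),
    n_samples_retained = sum(calls_all$retained$retained),
    mean_adjusted_R2 = mean(ev$agr$adjusted_R2, na.rm = TRUE),
    mean_abs_diff = mean(ev$agr$mean_abs_diff, na.rm = TRUE),
    repeatability = if (is.null(ev$rep_fit)) NA else ev$rep_fit$repeatability,
    subset_medians = ev$subs$results |>
      group_by(.data$subset_size) |>
      summarise(across(c("prop_estimable", "mean_adjusted_R2",
                         "mean_abs_diff"), median), .groups = "drop")
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline done")
  invisible(summary)
}
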