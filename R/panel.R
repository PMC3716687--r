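#' Default cluster geometry for simulated loci
#'
#' Mean theta positions and dispersions for the genotype clusters of each
#' locus class. Diploid SNP loci span almost the whole theta range
#' (means 0.05 / 0.50 / 0.95); MSV-3 loci, where the polymorphism sits on a
#' single paralogue of a duplicated region, have a compressed span of about
#' half that (means 0.05 / 0.275 / 0.50). Monomorphic loci share the SNP
#' geometry but segregate (almost) no B alleles.
#'
#' @param snp_means,msv3_means Length-3 numeric, strictly increasing cluster
#'   means for AA/AB/BB.
#' @param theta_sd Baseline within-cluster theta standard deviation.
#' @return Named list used by [simulate_panel()].
#' @export
panel_geometry <- function(snp_means = c(0.05, 0.50, 0.95),
                           msv3_means = c(0.05, 0.275, 0.50),
                           theta_sd = 0.02) {
  stopifnot(length(snp_means) == 3, length(msv3_means) == 3,
            all(diff(snp_means) > 0), all(diff(msv3_means) > 0),
            theta_sd >= 0)
  if (diff(range(snp_means)) < 0.7) {
    abort("SNP cluster means must span at least 0.7 in theta.")
  }
  if (diff(range(msv3_means)) > 0.55) {
    abort("MSV-3 cluster means must span at most 0.55 in theta.")
  }
  list(snp_means = snp_means, msv3_means = msv3_means, theta_sd = theta_sd)
}

# Draw n minor allele frequencies from a distribution spec: "uniform"
# (Unif(0.05, 0.5)), a single numeric (point mass), or a function(n).
draw_maf <- function(maf_distribution, n) {
  if (n == 0) return(numeric(0))
  m <- if (is.function(maf_distribution)) {
    maf_distribution(n)
  } else if (is.character(maf_distribution) && length(maf_distribution) == 1 &&
             maf_distribution == "uniform") {
    runif(n, 0.05, 0.5)
  } else if (is.numeric(maf_distribution) && length(maf_distribution) == 1) {
    rep(maf_distribution, n)
  } else {
    abort("`maf_distribution` must be \"uniform\", a single numeric, or a function(n).")
  }
  if (length(m) != n || any(!is.finite(m)) || any(m < 0 | m > 0.5)) {
    abort("MAF distribution must return n values in [0, 0.5].")
  }
  m
}

#' Simulate a locus panel mirroring a SNP-array manifest
#'
#' Generates `n_snp` diploid SNP loci, `n_msv3` MSV-3 loci (compressed theta
#' span), `n_mono` monomorphic loci and `n_discard` loci in the discard
#' classes (UNKNOWN / MSV5 / PSV / MITO / FAILED). Each locus carries its true
#' population B-allele frequency, true cluster geometry and a design score (a
#' GenTrain-like per-locus clustering quality in \[0, 1\]).
#'
#' SNP and MSV-3 frequencies are drawn from `maf_distribution` and assigned to
#' the B allele or its complement with equal probability; monomorphic loci are
#' fixed (frequency 0 or 1) or segregate at MAF < 0.01.
#'
#' @param n_snp,n_msv3,n_mono,n_discard Non-negative locus counts per class.
#' @param maf_distribution `"uniform"` (default, Unif(0.05, 0.5)), a single
#'   numeric point mass, or a `function(n)` returning MAFs in \[0, 0.5\].
#' @param geometry See [panel_geometry()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Tibble with one row per locus: `locus_id`, `classification`,
#'   `true_freq_B`, `theta_AA`, `theta_AB`, `theta_BB`, `theta_sd`,
#'   `design_score`.
#' @export
simulate_panel <- function(n_snp, n_msv3, n_mono, n_discard = 0,
                           maf_distribution = "uniform",
                           geometry = panel_geometry(), seed = NULL) {
  stopifnot(n_snp >= 0, n_msv3 >= 0, n_mono >= 0, n_discard >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_snp + n_msv3 + n_mono + n_discard
  if (n == 0) {
    return(tibble(
      locus_id = character(), classification = character(),
      true_freq_B = double(), theta_AA = double(), theta_AB = double(),
      theta_BB = double(), theta_sd = double(), design_score = double()
    ))
  }
  classification <- c(
    rep("SNP", n_snp), rep("MSV3", n_msv3), rep("MONO", n_mono),
    if (n_discard > 0)
      sample(c("UNKNOWN", "MSV5", "PSV", "MITO", "FAILED"), n_discard,
             replace = TRUE)
  )

  maf <- draw_maf(maf_distribution, n_snp + n_msv3)
  flip <- runif(n_snp + n_msv3) < 0.5
  freq_poly <- ifelse(flip, 1 - maf, maf)
  freq_mono <- if (n_mono > 0) {
    fixed <- runif(n_mono) < 0.8
    low <- runif(n_mono, 0, 0.01)
    ifelse(fixed, round(runif(n_mono)), ifelse(runif(n_mono) < 0.5, low, 1 - low))
  } else numeric(0)
  freq_disc <- runif(n_discard)
  true_freq_B <- c(freq_poly, freq_mono, freq_disc)

  msv3 <- classification == "MSV3"
  means <- matrix(rep(geometry$snp_means, each = n), nrow = n)
  means[msv3, ] <- matrix(rep(geometry$msv3_means, each = sum(msv3)), nrow = sum(msv3))

  tibble(
    locus_id = sprintf("L%05d", seq_len(n)),
    classification = classification,
    true_freq_B = true_freq_B,
    theta_AA = means[, 1],
    theta_AB = means[, 2],
    theta_BB = means[, 3],
    theta_sd = geometry$theta_sd,
    design_score = rbeta(n, 8, 2)
  )
}
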