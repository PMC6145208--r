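# Synthetic-data generators. These emulate the statistical structure of a
# fertile-reference sperm methylome cohort on a ~480k-probe methylation
# array: strongly unimodal per-CpG beta distributions with modes near 0.04
# (hypomethylated loci) and 0.95 (hypermethylated loci), tight reference
# intervals (IQR distribution mode ~0.03), technical replicates with small
# additive noise plus occasional outlier replicates, paired WGBS counts
# drawn binomially at moderate coverage, and probe intensities whose totals
# shrink with DNA concentration and bacterial-contamination fraction.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators with defaults
#' calibrated to the study conditions the pipeline is validated under. All
#' randomness in the generators is governed by `seed`.
#'
#' @param n_loci Number of CpG loci to simulate.
#' @param n_reference_samples Size of the fertile reference population
#'   (default 156).
#' @param hypo_fraction Fraction of unimodal loci with low (hypomethylated)
#'   means; the rest are hypermethylated.
#' @param mid_fraction Fraction of loci with intermediate means (uniform in
#'   \[0.35, 0.65\]); these are the loci where aberrance is detectable in
#'   both directions.
#' @param wide_fraction Fraction of loci with inflated between-sample spread
#'   (`wide_population_sd`); their reference intervals are too wide for any
#'   aberrance to be detectable.
#' @param hypo_mode,hyper_mode Centers of the hypo- and hypermethylated
#'   locus-mean distributions (beta-value units).
#' @param locus_jitter_sd SD of the jitter applied to locus means around
#'   their mode.
#' @param population_sd Per-locus between-sample SD (default 0.022, which
#'   puts the mode of the IQR distribution at about 1.349 x 0.022 ~ 0.03).
#' @param wide_population_sd Between-sample SD for the `wide_fraction` loci.
#' @param replicate_noise_sd Additive technical-replicate noise SD.
#' @param outlier_rate Probability that a technical replicate is an outlier
#'   replicate with `outlier_noise_sd` noise.
#' @param outlier_noise_sd Noise SD for outlier replicates.
#' @param coverage_mean,coverage_sd WGBS per-site coverage is a rounded
#'   normal with these parameters, clipped to at least 1 read.
#' @param array_intercept,array_slope Linear distortion injected into array
#'   measurements: `array = array_intercept + array_slope * truth + noise`.
#'   With the defaults (0.052, 0.948) the regression of WGBS on array
#'   recovers a reportable range of \[0.052, 1\].
#' @param array_noise_sd SD of the additive array measurement noise.
#' @param background_mean,background_sd Normal model for background-control
#'   probe intensities (per channel, arbitrary fluorescence units).
#' @param signal_mean Expected total probe intensity (M + U) at full DNA
#'   concentration with no contamination.
#' @param signal_cv Coefficient of variation of per-probe total signal.
#' @param beta_offset Offset used when recovering beta values from
#'   intensities, `M / (M + U + beta_offset)` (default 100, the
#'   conventional stabilizing constant).
#' @param gamma Intensity decay per unit contamination fraction: expected
#'   total signal is scaled by `(1 - gamma * contamination_fraction)`.
#' @param n_background Number of background-control probes per intensity
#'   table.
#' @param seed Integer RNG seed fixing all generator randomness.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_loci = 6690,
                       n_reference_samples = 156,
                       hypo_fraction = 0.5,
                       mid_fraction = 0.06,
                       wide_fraction = 0.003,
                       hypo_mode = 0.04,
                       hyper_mode = 0.95,
                       locus_jitter_sd = 0.01,
                       population_sd = 0.022,
                       wide_population_sd = 0.25,
                       replicate_noise_sd = 0.01,
                       outlier_rate = 0.056,
                       outlier_noise_sd = 0.06,
                       coverage_mean = 45,
                       coverage_sd = 20,
                       array_intercept = 0.052,
                       array_slope = 0.948,
                       array_noise_sd = 0.01,
                       background_mean = 200,
                       background_sd = 20,
                       signal_mean = 15000,
                       signal_cv = 0.1,
                       beta_offset = 100,
                       gamma = 1.9,
                       n_background = 600,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_loci >= 1, n_reference_samples >= 2,
              hypo_fraction >= 0, hypo_fraction <= 1,
              mid_fraction >= 0, wide_fraction >= 0,
              mid_fraction + wide_fraction <= 1,
              hypo_mode > 0, hypo_mode < 1, hyper_mode > 0, hyper_mode < 1,
              locus_jitter_sd > 0, population_sd > 0, wide_population_sd > 0,
              replicate_noise_sd >= 0, outlier_rate >= 0, outlier_rate <= 1,
              outlier_noise_sd >= 0, coverage_mean > 0, coverage_sd > 0,
              array_noise_sd >= 0, background_mean > 0, background_sd > 0,
              signal_mean > 0, signal_cv > 0, beta_offset >= 0, gamma >= 0,
              n_background >= 10)
  })
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic methylation data configuration\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Per-locus mean methylation levels plus spread class.
# Loci are assigned (deterministically under the current RNG state) to
# hypo / hyper / mid / wide classes.
locus_means <- function(config) {
  n <- config$n_loci
  u <- stats::runif(n)
  class <- ifelse(u < config$wide_fraction, "wide",
           ifelse(u < config$wide_fraction + config$mid_fraction, "mid",
           ifelse(u < config$wide_fraction + config$mid_fraction +
                    (1 - config$wide_fraction - config$mid_fraction) *
                    config$hypo_fraction, "hypo", "hyper")))
  mean <- numeric(n)
  mean[class == "hypo"] <- config$hypo_mode +
    stats::rnorm(sum(class == "hypo"), 0, config$locus_jitter_sd)
  mean[class == "hyper"] <- config$hyper_mode +
    stats::rnorm(sum(class == "hyper"), 0, config$locus_jitter_sd)
  mean[class == "mid"] <- stats::runif(sum(class == "mid"), 0.35, 0.65)
  mean[class == "wide"] <- stats::runif(sum(class == "wide"), 0.3, 0.7)
  sd <- ifelse(class == "wide", config$wide_population_sd,
               config$population_sd)
  list(mean = clip01(mean), sd = sd,
       locus_ids = sprintf("cg%07d", seq_len(n)))
}

#' Generate a reference population of methylomes
#'
#' Draws a beta matrix emulating a known-fertile reference cohort: each
#' locus has a mean near a hypo- or hypermethylated mode (with small
#' fractions of intermediate and high-variance loci) and per-sample values
#' are the locus mean plus Gaussian noise, truncated to \[0, 1\]. The
#' resulting per-locus distributions are strongly unimodal with tight
#' interquartile ranges.
#'
#' @param config A [sim_config()].
#' @return A beta matrix (`n_loci` x `n_reference_samples`).
#' @export
gen_reference_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reference_samples < 2)
    stop("need at least 2 reference samples")
  set.seed(config$seed)
  lm <- locus_means(config)
  n <- config$n_loci
  k <- config$n_reference_samples
  vals <- clip01(lm$mean + stats::rnorm(n * k, 0, lm$sd))
  beta_matrix(matrix(vals, nrow = n, ncol = k),
              lm$locus_ids, sprintf("ref_%03d", seq_len(k)))
}

#' Draw a "true" methylome from the population model
#'
#' Convenience generator for the per-locus truth vector of a single
#' individual: locus means plus population noise, like one column of
#' [gen_reference_population()] but with its own seed offset so samples are
#' independent of the reference cohort.
#'
#' @param config A [sim_config()].
#' @param seed_offset Integer added to `config$seed` for this draw.
#' @return Named numeric vector of methylation levels in \[0, 1\].
#' @export
gen_individual_truth <- function(config, seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lm <- locus_means(config)
  set.seed(config$seed + as.integer(seed_offset) + 1000L)
  truth <- clip01(lm$mean + stats::rnorm(config$n_loci, 0, lm$sd))
  names(truth) <- lm$locus_ids
  truth
}

#' Generate technical replicates of a methylome
#'
#' Each replicate is the truth vector plus additive Gaussian noise,
#' truncated to \[0, 1\]. With probability `outlier_rate` a replicate is an
#' outlier and uses `outlier_noise_sd` instead of `replicate_noise_sd`,
#' emulating the occasional noisy technical replicate seen in practice.
#'
#' @param truth Named numeric vector of true methylation levels in \[0, 1\].
#' @param n_reps Number of technical replicates (at least 2).
#' @param config A [sim_config()].
#' @param seed_offset Integer seed offset so different samples' replicate
#'   sets are independent.
#' @return A beta matrix (`length(truth)` x `n_reps`); outlier replicates
#'   are recorded in the `"outlier"` attribute.
#' @export
gen_technical_replicates <- function(truth, n_reps, config, seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"),
            all(truth >= 0 & truth <= 1, na.rm = TRUE))
  if (n_reps < 2) stop("need at least 2 technical replicates")
  set.seed(config$seed + as.integer(seed_offset) + 2000L)
  is_outlier <- stats::runif(n_reps) < config$outlier_rate
  sds <- ifelse(is_outlier, config$outlier_noise_sd, config$replicate_noise_sd)
  vals <- vapply(seq_len(n_reps), function(j)
    clip01(truth + stats::rnorm(length(truth), 0, sds[j])),
    numeric(length(truth)))
  ids <- names(truth)
  if (is.null(ids)) ids <- sprintf("cg%07d", seq_along(truth))
  out <- beta_matrix(vals, ids, sprintf("rep_%02d", seq_len(n_reps)))
  attr(out, "outlier") <- is_outlier
  out
}

#' Generate paired WGBS and array measurements of one methylome
#'
#' WGBS levels are binomial draws at a per-site coverage sampled from a
#' rounded normal (clipped to >= 1 read). Array levels are a linear
#' distortion of the truth, `array_intercept + array_slope * truth` plus
#' small noise, clipped to \[0, 1\]; regressing WGBS on array therefore
#' recovers a reportable-range lower cut-off of `array_intercept` (0.052 at
#' the defaults).
#'
#' @param truth Named numeric vector of true methylation levels in \[0, 1\].
#' @param config A [sim_config()].
#' @param seed_offset Integer seed offset.
#' @return A list with elements `wgbs` (methcounts-style data.frame, 0-based
#'   positions), `array` (named numeric vector of array levels) and `map`
#'   (data.frame linking `probe_id` to `chrom`, `pos`, `strand`).
#' @export
gen_paired_wgbs_array <- function(truth, config, seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"),
            all(truth >= 0 & truth <= 1, na.rm = TRUE))
  set.seed(config$seed + as.integer(seed_offset) + 3000L)
  n <- length(truth)
  coverage <- pmax(1L, as.integer(round(
    stats::rnorm(n, config$coverage_mean, config$coverage_sd))))
  level <- stats::rbinom(n, coverage, truth) / coverage
  array <- clip01(config$array_intercept + config$array_slope * truth +
                    stats::rnorm(n, 0, config$array_noise_sd))
  ids <- names(truth)
  if (is.null(ids)) ids <- sprintf("cg%07d", seq_len(n))
  names(array) <- ids
  pos <- 100L * seq_len(n)  # 0-based coordinates, arbitrary spacing
  wgbs <- data.frame(chrom = "chr1", pos = pos, strand = "+",
                     context = "CpG", level = level, coverage = coverage,
                     stringsAsFactors = FALSE)
  map <- data.frame(probe_id = ids, chrom = "chr1", pos = pos, strand = "+",
                    stringsAsFactors = FALSE)
  list(wgbs = wgbs, array = array, map = map)
}

#' Generate a probe intensity table for one sample
#'
#' Per-probe total signal is normal with mean
#' `signal_mean * concentration_fraction * (1 - gamma * contamination_fraction)`
#' and coefficient of variation `signal_cv`, split between the methylated
#' (M) and unmethylated (U) channels according to the truth level; each
#' channel additionally receives a background draw. Background-control
#' probes carry pure background in both channels. Increasing bacterial
#' contamination therefore depresses all probe intensities, including the
#' background controls — the failure mode the intensity-based (MU) QC is
#' designed to catch.
#'
#' @param truth Named numeric vector of true methylation levels in \[0, 1\].
#' @param concentration_fraction DNA concentration as a fraction of the
#'   standard full-concentration input, in \[0, 1\].
#' @param contamination_fraction Bacterial cell fraction in \[0, 1\];
#'   `gamma * contamination_fraction >= 1` is degenerate and rejected.
#' @param config A [sim_config()].
#' @param seed_offset Integer seed offset.
#' @return An intensity table data.frame (`probe_id`, `M`, `U`,
#'   `is_background_control`).
#' @export
gen_intensities <- function(truth, concentration_fraction,
                            contamination_fraction, config,
                            seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"),
            concentration_fraction >= 0, concentration_fraction <= 1,
            contamination_fraction >= 0, contamination_fraction <= 1,
            all(truth >= 0 & truth <= 1, na.rm = TRUE))
  if (config$gamma * contamination_fraction >= 1)
    stop("gamma * contamination_fraction >= 1: intensity model degenerate")
  set.seed(config$seed + as.integer(seed_offset) + 4000L)
  n <- length(truth)
  ids <- names(truth)
  if (is.null(ids)) ids <- sprintf("cg%07d", seq_len(n))
  mu_s <- config$signal_mean * concentration_fraction *
    (1 - config$gamma * contamination_fraction)
  s <- if (mu_s == 0) numeric(n) else
    pmax(0, stats::rnorm(n, mu_s, config$signal_cv * mu_s))
  bg <- function(k) pmax(0, stats::rnorm(k, config$background_mean,
                                         config$background_sd))
  m <- truth * s + bg(n)
  u <- (1 - truth) * s + bg(n)
  nb <- config$n_background
  data.frame(
    probe_id = c(ids, sprintf("neg_%04d", seq_len(nb))),
    M = c(m, bg(nb)),
    U = c(u, bg(nb)),
    is_background_control = rep(c(FALSE, TRUE), c(n, nb)),
    stringsAsFactors = FALSE)
}

#' Recover beta values from a probe intensity table
#'
#' Standard intensity-to-beta conversion `M / (M + U + offset)` over
#' non-control probes.
#'
#' @param tab Intensity table (see [read_intensity_table()]).
#' @param offset Stabilizing offset added to the denominator (default 100).
#' @return Named numeric vector of beta values in \[0, 1\].
#' @export
betas_from_intensities <- function(tab, offset = 100) {
  probes <- tab[!tab$is_background_control, , drop = FALSE]
  beta <- probes$M / (probes$M + probes$U + offset)
  names(beta) <- probes$probe_id
  beta
}
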