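# End-to-end validation run over the six assessment criteria:
# reportable range, reference interval, analytical sensitivity, precision,
# analytical specificity, and accuracy. Stages run in dependency order
# (reference population -> reportable range -> detectability -> calls ->
# precision / QC -> accuracy) on synthetic data drawn from a single
# sim_config, and the results are collected into one serializable report.

safe_cor_test <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Analytical-sensitivity arithmetic: concentration to cell count
#'
#' Converts a minimum workable DNA concentration into the total
#' post-conversion DNA mass, the pre-conversion input mass, and the
#' corresponding minimum number of haploid cells.
#'
#' @param concentration Minimum DNA concentration (ng/ul).
#' @param volume Loaded sample volume (ul; default 15).
#' @param conversion_loss Fraction of DNA lost to bisulfite conversion, in
#'   \[0, 1) (default 0.9).
#' @param dna_per_cell DNA mass per haploid cell (pg; default 3).
#' @return A list with `total_ng` (post-conversion mass,
#'   `concentration * volume`), `input_ng` (pre-conversion input,
#'   `total_ng / (1 - conversion_loss)`), and `min_cells`
#'   (`input_ng * 1000 / dna_per_cell`).
#' @examples
#' sensitivity_arithmetic(0.5, 15, 0.9, 3)  # 7.5 ng, 75 ng, 25000 cells
#' @export
sensitivity_arithmetic <- function(concentration, volume = 15,
                                   conversion_loss = 0.9, dna_per_cell = 3) {
  stopifnot(concentration > 0, volume > 0, dna_per_cell > 0,
            conversion_loss >= 0, conversion_loss < 1)
  total_ng <- concentration * volume
  input_ng <- total_ng / (1 - conversion_loss)
  list(total_ng = total_ng, input_ng = input_ng,
       min_cells = input_ng * 1000 / dna_per_cell)
}

#' Convert a per-call inconsistency rate to "1 in N calls"
#'
#' @param rate Per-call inconsistency rate in (0, 1) (e.g. 0.003).
#' @return N such that one inconsistency is expected every N calls
#'   (`1 / rate`; 0.003 gives about 333).
#' @export
inconsistency_odds <- function(rate) {
  stopifnot(rate > 0, rate < 1)
  1 / rate
}

#' Run the full technical-validation pipeline on synthetic data
#'
#' Generates every input from `config` and exercises all six validation
#' criteria, returning a structured report. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param t Aberrance threshold (default 0.2).
#' @param p_cutoff Detection p-value cutoff for failed probes (default
#'   0.01).
#' @param fail_fraction Failed-probe fraction above which a sample fails
#'   (default 0.05).
#' @param t_grid Threshold grid for the precision sweep.
#' @param pt_rate,pt_slack,pt_pass_fraction Proficiency-testing parameters
#'   (see [pt_evaluate()]).
#' @param min_cov,max_cov Inclusive WGBS coverage bounds for the
#'   gold-standard comparison.
#' @param n_paired_samples Number of paired WGBS/array samples (default 8).
#' @param n_precision_samples,n_precision_reps Precision design (default 6
#'   samples x 6 technical replicates).
#' @param concentration_grid DNA concentrations assayed for sensitivity
#'   (ng/ul); `standard_concentration` is the full-strength input they are
#'   measured against.
#' @param standard_concentration Standard (full) DNA concentration (ng/ul).
#' @param sample_volume,conversion_loss,dna_per_cell Arguments for
#'   [sensitivity_arithmetic()].
#' @param contamination_grid Bacterial contamination fractions for the
#'   specificity experiment.
#' @param n_specificity_samples Number of specificity samples (default 8;
#'   each is split across the contamination grid).
#' @return An object of class `validation_report`.
#' @export
run_validation <- function(config = sim_config(),
                           t = 0.2,
                           p_cutoff = 0.01,
                           fail_fraction = 0.05,
                           t_grid = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4),
                           pt_rate = 0.003, pt_slack = 0.2,
                           pt_pass_fraction = 0.8,
                           min_cov = 30, max_cov = 100,
                           n_paired_samples = 8,
                           n_precision_samples = 6, n_precision_reps = 6,
                           concentration_grid =
                             c(0, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 10),
                           standard_concentration = 10,
                           sample_volume = 15, conversion_loss = 0.9,
                           dna_per_cell = 3,
                           contamination_grid =
                             c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                           n_specificity_samples = 8) {
  stopifnot(inherits(config, "sim_config"))

  ## -- Reference population and per-locus intervals ---------------------
  ref_pop <- gen_reference_population(config)
  ref_tab <- build_reference(ref_pop)
  iqr_summary <- summarize_iqr(ref_tab)

  ## -- Reportable range and accuracy (paired WGBS / array) --------------
  fits <- vector("list", n_paired_samples)
  pearson <- numeric(n_paired_samples)
  n_pairs <- integer(n_paired_samples)
  for (s in seq_len(n_paired_samples)) {
    truth <- gen_individual_truth(config, s)
    paired <- gen_paired_wgbs_array(truth, config, s)
    pairs <- filter_comparable_loci(paired$wgbs, paired$array, paired$map,
                                    min_cov, max_cov)
    fits[[s]] <- fit_reportable_range(pairs)
    pearson[s] <- accuracy_correlation(pairs)
    n_pairs[s] <- nrow(pairs)
  }
  range_overall <- aggregate_reportable_range(fits)
  reportable_low <- range_overall[1]
  per_sample_fits <- data.frame(
    sample_id = sprintf("paired_%d", seq_len(n_paired_samples)),
    n = n_pairs,
    a = vapply(fits, `[[`, numeric(1), "a"),
    b = vapply(fits, `[[`, numeric(1), "b"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
    R_low = vapply(fits, `[[`, numeric(1), "R_low"),
    R_high = vapply(fits, `[[`, numeric(1), "R_high"),
    pearson_r = pearson,
    stringsAsFactors = FALSE)

  ## -- Detectability classification -------------------------------------
  ref_tab <- classify_detectability(ref_tab, t, reportable_low)
  det <- ref_tab$detectability[!is.na(ref_tab$detectability)]
  detectable_fraction <- mean(det != "undetectable")
  one_direction_fraction <-
    mean(det[det != "undetectable"] %in% c("hyper_only", "hypo_only"))

  ## -- Precision ---------------------------------------------------------
  rep_sets <- lapply(seq_len(n_precision_samples), function(s) {
    truth <- gen_individual_truth(config, 100L + s)
    gen_technical_replicates(truth, n_precision_reps, config, 100L + s)
  })
  names(rep_sets) <- sprintf("precision_%d", seq_len(n_precision_samples))
  sweep <- threshold_sweep(rep_sets, ref_tab, t_grid, reportable_low)
  call_sets <- lapply(rep_sets, function(mat)
    lapply(colnames(mat), function(rep_id)
      call_sample(mat[, rep_id], ref_tab, t, reportable_low, rep_id)))
  s_jt <- vapply(call_sets, function(cs) sample_similarity(cs)$S_jt,
                 numeric(1))
  mean_s_jt <- mean(s_jt)
  pt <- pt_evaluate(call_sets[[1]], pt_rate, pt_slack, pt_pass_fraction,
                    m = config$n_loci)
  pairwise <- pairwise_differences(call_sets[[1]])

  ## -- Analytical sensitivity (dilution series) -------------------------
  conc_grid <- sort(concentration_grid)
  n_sens <- 6L
  sens_pass <- matrix(NA, n_sens, length(conc_grid))
  sens_frac <- matrix(NA_real_, n_sens, length(conc_grid))
  for (s in seq_len(n_sens)) {
    truth <- gen_individual_truth(config, 200L + s)
    for (k in seq_along(conc_grid)) {
      frac <- min(1, conc_grid[k] / standard_concentration)
      intens <- gen_intensities(truth, frac, 0, config,
                                seed_offset = 200L + 10L * s + k)
      pv <- detection_pvalues(intens)
      fr <- failed_probe_mask(pv, p_cutoff)$fraction
      sens_frac[s, k] <- fr
      sens_pass[s, k] <- sample_sensitivity_pass(fr, fail_fraction)
    }
  }
  failed_per_conc <- colSums(!sens_pass)
  # all-clean concentrations: this level and every higher one failure-free
  clean <- rev(cumprod(rev(failed_per_conc == 0))) == 1
  if (!any(clean))
    stop("no concentration level passes the sensitivity screen")
  first_clean <- which(clean)[1]
  # conservative margin: one grid step above the lowest passing level
  threshold_idx <- min(first_clean + 1L, length(conc_grid))
  concentration_threshold <- conc_grid[threshold_idx]
  arithmetic <- sensitivity_arithmetic(concentration_threshold,
                                       sample_volume, conversion_loss,
                                       dna_per_cell)

  ## -- Analytical specificity (contamination series) --------------------
  spec <- expand.grid(sample = seq_len(n_specificity_samples),
                      level = contamination_grid)
  spec$count <- NA_real_
  spec$mu <- NA_real_
  spec$failed_probe_fraction <- NA_real_
  for (r in seq_len(nrow(spec))) {
    s <- spec$sample[r]
    lvl <- spec$level[r]
    truth <- gen_individual_truth(config, 300L + s)
    intens <- gen_intensities(truth, 1, lvl, config,
                              seed_offset = 300L + 10L * s +
                                match(lvl, contamination_grid))
    pv <- detection_pvalues(intens)
    mask <- failed_probe_mask(pv, p_cutoff)
    beta <- betas_from_intensities(intens, config$beta_offset)
    beta[mask$failed] <- NA  # failed probes removed before calling
    calls <- call_sample(beta, ref_tab, t, reportable_low,
                         sprintf("spec_%d_%g", s, lvl))
    spec$count[r] <- aberrant_count(calls)
    spec$mu[r] <- mu_statistic(intens)
    spec$failed_probe_fraction[r] <- mask$fraction
  }
  normal_range <- normal_aberrant_range(spec$count[spec$level == 0])
  spec$count_failed <- spec$count < normal_range[1] |
    spec$count > normal_range[2]
  mu_threshold <- learn_mu_threshold(spec$mu[spec$count_failed],
                                     spec$mu[!spec$count_failed])
  spec$mu_pass <- spec$mu >= mu_threshold
  cor_all <- safe_cor_test(spec$count, spec$level)
  cor_passed <- safe_cor_test(spec$count[spec$mu_pass],
                              spec$level[spec$mu_pass])

  ## -- Assemble ----------------------------------------------------------
  report <- list(
    reportable_range = list(
      per_sample = per_sample_fits,
      overall_low = range_overall[1],
      overall_high = range_overall[2]),
    reference_interval = list(
      n_loci = nrow(ref_tab),
      iqr_mode = iqr_summary$mode,
      frac_ci_below_0.1 = iqr_summary$frac_ci_below,
      detectable_fraction = detectable_fraction,
      one_direction_fraction = one_direction_fraction,
      t = t),
    sensitivity = list(
      concentration_grid = conc_grid,
      failed_samples_per_concentration = unname(failed_per_conc),
      mean_failed_probe_fraction = unname(colMeans(sens_frac)),
      concentration_threshold = concentration_threshold,
      total_ng = arithmetic$total_ng,
      input_ng = arithmetic$input_ng,
      min_cells = arithmetic$min_cells),
    precision = list(
      t = t,
      S_jt = unname(s_jt),
      mean_S_jt = mean_s_jt,
      inconsistency_rate = 1 - mean_s_jt,
      sweep = sweep,
      pt_allowance = pt$allowance,
      pt_pass = pt$pass,
      pt_frac_pass = pt$frac_pass,
      pairwise_differences_sample1 = unname(pairwise)),
    specificity = list(
      replicates = spec,
      normal_count_range = normal_range,
      mu_threshold = mu_threshold,
      n_failed = sum(spec$count_failed),
      cor_count_contamination_all = cor_all,
      cor_count_contamination_passed = cor_passed),
    accuracy = list(
      pearson_r = pearson,
      mean_r = mean(pearson),
      sd_r = stats::sd(pearson)),
    provenance = list(
      config = unclass(config),
      seed = config$seed,
      version = as.character(utils::packageVersion("methvalid"))))
  structure(report, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Technical validation report (synthetic run)\n")
  cat(sprintf("  reportable range     [%.3f, %.3f]\n",
              x$reportable_range$overall_low,
              x$reportable_range$overall_high))
  cat(sprintf("  accuracy             mean Pearson r = %.3f (sd %.3f)\n",
              x$accuracy$mean_r, x$accuracy$sd_r))
  cat(sprintf("  reference interval   IQR mode %.3f; %.1f%% detectable\n",
              x$reference_interval$iqr_mode,
              100 * x$reference_interval$detectable_fraction))
  cat(sprintf("  precision            mean S_jt = %.5f at t = %.2f\n",
              x$precision$mean_S_jt, x$precision$t))
  cat(sprintf("  sensitivity          threshold %.3g ng/ul (%.0f cells)\n",
              x$sensitivity$concentration_threshold,
              x$sensitivity$min_cells))
  cat(sprintf("  specificity          MU threshold %.3f (%d failed)\n",
              x$specificity$mu_threshold, x$specificity$n_failed))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Reports are written as pretty-printed JSON with full numeric precision
#' and no timestamps, so a run with a fixed seed produces byte-identical
#' files.
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "string", pretty = TRUE)
  invisible(path)
}

#' Read a serialized validation report
#'
#' @param path Path to a JSON report written by [write_validation_report()].
#' @return A `validation_report` object.
#' @export
read_validation_report <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE),
            class = "validation_report")
}
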