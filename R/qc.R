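# Sample-level quality control.
#
# Sensitivity QC: the total signal M + U of a probe that detected DNA
# should stand out from background fluorescence. Background-control
# intensities are modelled as Normal(mu, sigma) per channel; under the
# null that a probe carries background only, M + U is the sum of two
# background draws, Normal(2 mu, 2 sigma^2), giving the detection p-value
#   p = 1 - Phi((M + U - 2 mu) / (sqrt(2) sigma)).
#
# Specificity QC: contamination depresses all intensities, including the
# background controls, so detection p-values miss it. The MU statistic
#   MU = log2(sqrt(median(M) * median(U)))
# summarizes overall sample intensity; a max-margin threshold learned from
# samples labelled failed/passed by their aberrant-call counts flags
# low-intensity samples.

#' Detection p-values from background-control probes
#'
#' Estimates the background mean and SD from the pooled per-channel
#' intensities of background-control rows, then computes for each
#' non-control probe the probability that its total signal `M + U` would
#' arise from background fluorescence alone.
#'
#' @param intensities Intensity table (see [read_intensity_table()]) with
#'   at least 10 background-control rows.
#' @return Named numeric vector of p-values in (0, 1), one per non-control
#'   probe.
#' @export
detection_pvalues <- function(intensities) {
  ctrl <- intensities[intensities$is_background_control, , drop = FALSE]
  if (nrow(ctrl) < 10)
    stop("need at least 10 background-control rows, found ", nrow(ctrl))
  pooled <- c(ctrl$M, ctrl$U)
  mu <- mean(pooled)
  sigma <- stats::sd(pooled)
  if (sigma == 0) stop("degenerate background controls (zero variance)")
  probes <- intensities[!intensities$is_background_control, , drop = FALSE]
  p <- stats::pnorm(probes$M + probes$U, mean = 2 * mu,
                    sd = sqrt(2) * sigma, lower.tail = FALSE)
  names(p) <- probes$probe_id
  p
}

#' Failed-probe mask from detection p-values
#'
#' A probe fails when its detection p-value is strictly greater than the
#' cutoff (a probe at exactly the cutoff passes).
#'
#' @param pvalues Numeric vector of detection p-values.
#' @param cutoff Failure cutoff (default 0.01).
#' @return A list with `failed` (logical mask) and `fraction`
#'   (failed / total).
#' @export
failed_probe_mask <- function(pvalues, cutoff = 0.01) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  failed <- pvalues > cutoff
  list(failed = failed, fraction = mean(failed))
}

#' Sample-level sensitivity pass/fail
#'
#' A sample fails when strictly more than `cutoff` (default 5%) of its
#' probes failed detection.
#'
#' @param fraction Failed-probe fraction in \[0, 1\].
#' @param cutoff Failure cutoff (default 0.05).
#' @return `TRUE` (pass) or `FALSE` (fail); vectorized.
#' @export
sample_sensitivity_pass <- function(fraction, cutoff = 0.05) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  fraction <= cutoff
}

#' Sample intensity statistic MU
#'
#' The log2 geometric mean of the median methylated and unmethylated probe
#' intensities of a sample, `log2(sqrt(median(M) * median(U)))`, computed
#' over non-control probes. Low MU signals an under-performing sample
#' (degraded input, contamination) even when detection p-values look fine.
#'
#' @param intensities Intensity table.
#' @return MU in log2 intensity units.
#' @export
mu_statistic <- function(intensities) {
  probes <- intensities[!intensities$is_background_control, , drop = FALSE]
  med_m <- stats::median(probes$M)
  med_u <- stats::median(probes$U)
  if (!(med_m > 0 && med_u > 0))
    stop("median intensities must be positive to compute MU")
  log2(sqrt(med_m * med_u))
}

#' Normal range for aberrant-call counts of clean replicates
#'
#' The 99% normal range of per-replicate aberrant-call counts among
#' uncontaminated replicates, using a normal approximation
#' `mean +/- z_{0.995} * sd` floored at 0 (the handful of replicates
#' available makes empirical 0.5/99.5 percentiles meaningless).
#'
#' @param counts Integer vector of aberrant-call counts (>= 3 values).
#' @param level Coverage of the range (default 0.99).
#' @return Numeric `c(lower, upper)`.
#' @export
normal_aberrant_range <- function(counts, level = 0.99) {
  if (length(counts) < 3) stop("need at least 3 counts")
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- mean(counts)
  s <- stats::sd(counts)
  c(max(0, m - z * s), m + z * s)
}

#' Learn the max-margin MU failure threshold
#'
#' Given MU values of samples labelled failed and passed (by their
#' aberrant-call counts falling outside/inside the normal range), returns
#' the one-dimensional maximum-margin separator: the midpoint between the
#' largest failed MU and the smallest passed MU. Samples with MU below the
#' threshold are labelled failed. Errors if the groups overlap.
#'
#' @param mu_failed,mu_passed Non-empty numeric vectors of MU values.
#' @return The threshold (log2 intensity units).
#' @export
learn_mu_threshold <- function(mu_failed, mu_passed) {
  if (length(mu_failed) == 0 || length(mu_passed) == 0)
    stop("both groups must be non-empty")
  hi_fail <- max(mu_failed)
  lo_pass <- min(mu_passed)
  if (hi_fail >= lo_pass)
    stop(sprintf(
      "failed and passed MU groups are not separable (max failed %.4g >= min passed %.4g)",
      hi_fail, lo_pass))
  (hi_fail + lo_pass) / 2
}
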