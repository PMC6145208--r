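# Replicate-precision statistics. At a single CpG with n technical
# replicates of which x are called aberrant, the call similarity is
#   S = max(x, n - x) / n,
# ranging from 1 (perfect agreement) down to 0.5 (the threshold perfectly
# bisects the calls). Averaging S over the m profiled CpGs gives the
# per-sample similarity S_jt: the empirical probability that one more
# technical replicate would produce a normal/aberrant call consistent with
# the previous ones at a random CpG.

#' Per-locus call similarity
#'
#' @param x Number of replicates called aberrant at the locus (0 <= x <= n).
#' @param n Number of technical replicates (>= 1). Both arguments are
#'   vectorized.
#' @return `max(x, n - x) / n`, in \[0.5, 1\].
#' @examples
#' locus_similarity(6, 6)  # 1: perfect agreement
#' locus_similarity(3, 6)  # 0.5: worst case
#' @export
locus_similarity <- function(x, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n")
  pmax(x, n - x) / n
}

#' Per-sample replicate similarity from a set of call sets
#'
#' Computes per-locus aberrant-replicate counts from the technical
#' replicates of one sample and averages the per-locus similarity over all
#' m evaluated loci — including loci never aberrant in any replicate, which
#' contribute similarity 1. Loci that are `not_evaluable` in some
#' replicates use the evaluable replicates only; loci evaluable in no
#' replicate are dropped from m.
#'
#' @param calls List of `aberrant_calls` objects (the technical replicates
#'   of one sample, >= 2), sharing a locus universe and threshold.
#' @return A list with `S_jt` (the mean similarity), `S_i` (per-locus
#'   similarity), `x_i` (per-locus aberrant counts), `n_i` (per-locus
#'   evaluable replicate counts), `m` (loci evaluated), `n_reps`, and `t`.
#' @export
sample_similarity <- function(calls) {
  stopifnot(length(calls) >= 2,
            all(vapply(calls, inherits, TRUE, "aberrant_calls")))
  universe <- names(calls[[1]]$states)
  for (cs in calls[-1])
    if (!setequal(names(cs$states), universe))
      stop("replicates are over different locus universes")
  states <- vapply(calls, function(cs) cs$states[universe],
                   character(length(universe)))
  aberrant <- states == "hyper" | states == "hypo"
  evaluable <- states != "not_evaluable"
  x_i <- rowSums(aberrant & evaluable)
  n_i <- rowSums(evaluable)
  keep <- n_i >= 1
  if (!any(keep)) stop("no evaluable loci (m = 0)")
  s_i <- locus_similarity(x_i[keep], n_i[keep])
  list(S_jt = mean(s_i), S_i = s_i, x_i = x_i[keep], n_i = n_i[keep],
       m = sum(keep), n_reps = length(calls), t = calls[[1]]$t)
}

#' Pairwise set-difference matrix between technical replicates
#'
#' @param calls List of `aberrant_calls` objects over a shared universe.
#' @return Symmetric integer matrix of [call_set_difference()] counts with
#'   zero diagonal.
#' @export
pairwise_differences <- function(calls) {
  k <- length(calls)
  d <- matrix(0L, k, k)
  ids <- vapply(calls, function(cs) cs$sample_id, "")
  dimnames(d) <- list(ids, ids)
  if (k > 1)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      d[i, j] <- d[j, i] <- call_set_difference(calls[[i]], calls[[j]])
  d
}

#' Replicate similarity as a function of the aberrance threshold
#'
#' Recomputes aberrant calls and the per-sample similarity S_jt at every
#' threshold in `t_grid`, for one or more samples' replicate sets.
#'
#' @param replicates Either a beta matrix (loci x replicates, one sample)
#'   or a named list of such matrices (one per sample).
#' @param reference Reference interval table from [build_reference()].
#' @param t_grid Numeric vector of thresholds in (0, 1).
#' @param reportable_low Lower bound of the reportable range.
#' @return A `data.frame` with one row per threshold: column `t`, one
#'   similarity column per sample, and `mean` (across samples).
#' @export
threshold_sweep <- function(replicates, reference, t_grid,
                            reportable_low = 0) {
  if (length(t_grid) == 0) stop("empty threshold grid")
  if (!(all(t_grid > 0 & t_grid < 1))) stop("t_grid must lie in (0, 1)")
  if (is.matrix(replicates)) replicates <- list(sample_1 = replicates)
  if (is.null(names(replicates)))
    names(replicates) <- sprintf("sample_%d", seq_along(replicates))
  sweep_one <- function(mat) {
    vapply(t_grid, function(t) {
      calls <- lapply(colnames(mat), function(rep_id)
        call_sample(mat[, rep_id], reference, t, reportable_low, rep_id))
      sample_similarity(calls)$S_jt
    }, numeric(1))
  }
  per_sample <- vapply(replicates, sweep_one, numeric(length(t_grid)))
  per_sample <- matrix(per_sample, nrow = length(t_grid),
                       dimnames = list(NULL, names(replicates)))
  out <- data.frame(t = t_grid, per_sample, check.names = FALSE)
  out$mean <- rowMeans(per_sample)
  out
}

#' Proficiency-testing evaluation of new replicates
#'
#' Proficiency testing re-runs known samples and requires that the number
#' of aberrant-call differences stays within an allowance derived from the
#' established per-call inconsistency rate: each replicate is allowed
#' `floor(m * baseline_rate * (1 + slack))` differences, its statistic
#' being the median of its pairwise set-difference counts against all prior
#' replicates. The run passes when at least `pass_fraction` of the
#' evaluated replicates pass. The first replicate serves as baseline only.
#'
#' @param new_replicates Ordered list of `aberrant_calls` objects (>= 2);
#'   element 1 is the pre-existing baseline.
#' @param baseline_rate Established per-call inconsistency rate, in (0, 1)
#'   (e.g. 0.003).
#' @param slack Relative tolerance on the allowance (e.g. 0.2 for 20%).
#' @param pass_fraction Required fraction of passing replicates, in (0, 1].
#' @param m Number of candidate loci a difference can occur at.
#' @return A list with `allowance`, per-replicate `detail` (data.frame:
#'   `sample_id`, `median_differences`, `pass`), `frac_pass`, and `pass`
#'   (overall outcome).
#' @export
pt_evaluate <- function(new_replicates, baseline_rate, slack = 0.2,
                        pass_fraction = 0.8, m) {
  stopifnot(baseline_rate > 0, baseline_rate < 1, slack >= 0,
            pass_fraction > 0, pass_fraction <= 1, m >= 1)
  if (length(new_replicates) < 2)
    stop("need at least one prior replicate to compare against")
  allowance <- floor(m * baseline_rate * (1 + slack))
  k <- length(new_replicates)
  stat <- vapply(2:k, function(i) {
    diffs <- vapply(seq_len(i - 1), function(j)
      call_set_difference(new_replicates[[i]], new_replicates[[j]]),
      numeric(1))
    stats::median(diffs)
  }, numeric(1))
  ids <- vapply(new_replicates[-1], function(cs) cs$sample_id, "")
  pass_rep <- stat <= allowance
  detail <- data.frame(sample_id = ids, median_differences = stat,
                       pass = pass_rep, stringsAsFactors = FALSE)
  frac <- mean(pass_rep)
  list(allowance = allowance, detail = detail, frac_pass = frac,
       pass = frac >= pass_fraction)
}
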