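# Aberrant-methylation calling against per-locus reference intervals.

#' Call aberrant methylation for one sample
#'
#' A level is called `hyper` when it exceeds the locus's upper 95%
#' reference bound by more than `t`, and `hypo` when it is more than `t`
#' below the lower bound. Inequalities are strict: a value exactly at
#' `upper + t` (or `lower - t`) is normal. Measured values below the
#' reportable range cannot be quantified exactly, only bounded above by
#' `reportable_low`; they are therefore compared worst-case, i.e. a hypo
#' call additionally requires `reportable_low < lower - t` so that the
#' entire interval `[0, reportable_low]` lies below the call threshold.
#' Operationally: `hypo` iff `max(beta, reportable_low) < lower - t`.
#' Missing levels and loci with missing reference bounds are
#' `not_evaluable`.
#'
#' @param beta Named numeric vector of methylation levels for one sample;
#'   names must match `reference$locus_id` (same set, any order).
#' @param reference Reference interval table from [build_reference()].
#' @param t Aberrance threshold in (0, 1).
#' @param reportable_low Lower bound of the assay's reportable range.
#' @param sample_id Identifier stored in the call set.
#' @return An object of class `aberrant_calls`: list with `sample_id`,
#'   `states` (named character vector over all loci, values in
#'   `normal`/`hyper`/`hypo`/`not_evaluable`), `t`, and `reportable_low`.
#' @export
call_sample <- function(beta, reference, t = 0.2, reportable_low = 0,
                        sample_id = "sample") {
  if (!(t > 0 && t < 1)) stop("t must be in (0, 1)")
  if (is.null(names(beta)))
    stop("'beta' must be named by locus id")
  if (!setequal(names(beta), reference$locus_id))
    stop("locus mismatch between beta vector and reference table")
  beta <- beta[reference$locus_id]
  hyper <- beta > reference$upper + t
  hypo <- pmax(beta, reportable_low) < reference$lower - t
  states <- ifelse(hyper, "hyper", ifelse(hypo, "hypo", "normal"))
  states[is.na(beta) | is.na(reference$lower) | is.na(reference$upper)] <-
    "not_evaluable"
  names(states) <- reference$locus_id
  structure(list(sample_id = sample_id, states = states, t = t,
                 reportable_low = reportable_low),
            class = "aberrant_calls")
}

#' @export
print.aberrant_calls <- function(x, ...) {
  tab <- table(factor(x$states,
                      levels = c("normal", "hyper", "hypo", "not_evaluable")))
  cat(sprintf("Aberrant methylation calls for '%s' (t = %g)\n",
              x$sample_id, x$t))
  print(tab)
  invisible(x)
}

#' Loci called aberrant in a call set
#'
#' @param calls An `aberrant_calls` object.
#' @return Character vector of locus ids with state `hyper` or `hypo`.
#' @export
aberrant_loci <- function(calls) {
  stopifnot(inherits(calls, "aberrant_calls"))
  names(calls$states)[calls$states %in% c("hyper", "hypo")]
}

#' Number of aberrantly methylated loci in a call set
#'
#' @param calls An `aberrant_calls` object.
#' @return Integer count of loci called `hyper` or `hypo`.
#' @export
aberrant_count <- function(calls) {
  length(aberrant_loci(calls))
}

#' Set-difference dissimilarity between two call sets
#'
#' The number of loci called aberrant in one call set or the other but not
#' both — the cardinality of the symmetric difference of the two
#' aberrant-locus sets. Sets are taken over loci, ignoring direction: a
#' locus hyper in one replicate and hypo in the other is aberrant in both
#' and contributes no difference.
#'
#' @param a,b `aberrant_calls` objects over the same locus universe.
#' @return Integer dissimilarity count.
#' @export
call_set_difference <- function(a, b) {
  stopifnot(inherits(a, "aberrant_calls"), inherits(b, "aberrant_calls"))
  if (!setequal(names(a$states), names(b$states)))
    stop("call sets are over different locus universes")
  sa <- aberrant_loci(a)
  sb <- aberrant_loci(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}
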