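# Shared fixtures: small synthetic configurations and hand-built tables.

small_config <- function(seed = 42, ...) {
  sim_config(n_loci = 1500, seed = seed, ...)
}

# A reference table with explicitly chosen bounds, for calling tests.
manual_reference <- function(lower, upper, locus_ids = NULL) {
  n <- length(lower)
  if (is.null(locus_ids)) locus_ids <- sprintf("L%03d", seq_len(n))
  data.frame(locus_id = locus_ids, n = 100,
             min = lower, q1 = lower, median = (lower + upper) / 2,
             q3 = upper, max = upper, lower = lower, upper = upper,
             detectability = NA_character_, stringsAsFactors = FALSE)
}

# Build an aberrant_calls object directly from a set of aberrant loci.
manual_calls <- function(universe, aberrant, sample_id = "s",
                         t = 0.2, direction = "hyper") {
  states <- stats::setNames(rep("normal", length(universe)), universe)
  states[aberrant] <- direction
  structure(list(sample_id = sample_id, states = states, t = t,
                 reportable_low = 0),
            class = "aberrant_calls")
}

# Intensity table whose background controls have exactly the given pooled
# mean and SD, so detection p-values can be checked against closed forms.
manual_intensity_table <- function(probe_MU_totals, bg_mean = 200,
                                   bg_sd = 20, n_controls = 12) {
  z <- rep(c(-1, 1), n_controls)
  z <- z / stats::sd(z)
  bg <- bg_mean + bg_sd * z
  n <- length(probe_MU_totals)
  data.frame(
    probe_id = c(sprintf("p%03d", seq_len(n)),
                 sprintf("neg%03d", seq_len(n_controls))),
    M = c(probe_MU_totals / 2, bg[seq_len(n_controls)]),
    U = c(probe_MU_totals / 2, bg[n_controls + seq_len(n_controls)]),
    is_background_control = rep(c(FALSE, TRUE), c(n, n_controls)),
    stringsAsFactors = FALSE)
}
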