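# Independent brute-force oracles used to cross-check the package's
# computations. These are deliberately naive and share no code with the
# implementation.

# Linear-interpolation quantile at position (n - 1) * p between order
# statistics, written out by hand.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo + 1] + (h - lo) * (x[hi + 1] - x[lo + 1])
  }, numeric(1))
}

# Symmetric-difference cardinality by direct membership testing.
oracle_setdiff_count <- function(a, b) {
  sum(!(a %in% b)) + sum(!(b %in% a))
}

# One-dimensional max-margin separator by exhaustive search over the
# midpoints of consecutive sorted values: among cuts that classify every
# failed value below and every passed value above, pick the one with the
# largest minimum distance to any training point.
oracle_margin_threshold <- function(failed, passed) {
  pts <- sort(c(failed, passed))
  cuts <- (pts[-1] + pts[-length(pts)]) / 2
  valid <- vapply(cuts, function(cut)
    all(failed < cut) && all(passed > cut), logical(1))
  cuts <- cuts[valid]
  margins <- vapply(cuts, function(cut) min(abs(pts - cut)), numeric(1))
  cuts[which.max(margins)]
}

# OLS slope/intercept from the normal equations, written out by hand.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(a = a, b = b)
}

# A small reference table built directly from per-locus value lists using
# the quantile oracle.
oracle_reference_row <- function(vals) {
  q <- oracle_quantile(vals, c(0, 0.25, 0.5, 0.75, 1, 0.025, 0.975))
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       lower = q[6], upper = q[7])
}
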