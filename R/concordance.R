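# Gold-standard concordance: pairing array measurements with WGBS sites,
# coverage filtering, accuracy correlation, and linear reportable-range
# calibration. The model is y_i = a + b x_i + e with y the WGBS level and
# x the array level at CpG i; the reportable range is where the fit stays
# inside [0, 1]:
#   R_low  = max(0, -a / b)        (x at y = 0)
#   R_high = min(1, (1 - a) / b)   (x at y = 1)

#' Pair array levels with WGBS sites and filter by coverage
#'
#' Keeps loci present on both platforms whose WGBS coverage lies in
#' `[min_cov, max_cov]` (inclusive). Low-coverage sites have coarse level
#' resolution (with 3 reads only 0, 1/3, 2/3, 1 are representable);
#' unusually high coverage flags technical artifacts. The probe-to-site
#' mapping is explicit: either `map` links `probe_id` to
#' `(chrom, pos, strand)`, or, when `map` is `NULL`, the names of `array`
#' are taken to be `chrom:pos:strand` keys.
#'
#' @param wgbs WGBS site table (see [read_wgbs_sites()]).
#' @param array Named numeric vector of array methylation levels.
#' @param map Optional `data.frame` with columns `probe_id`, `chrom`,
#'   `pos`, `strand`.
#' @param min_cov,max_cov Inclusive coverage bounds (defaults 30 and 100).
#' @return A `data.frame` with columns `probe_id`, `x` (array level), `y`
#'   (WGBS level) and `coverage`.
#' @export
filter_comparable_loci <- function(wgbs, array, map = NULL,
                                   min_cov = 30, max_cov = 100) {
  site_key <- paste(wgbs$chrom, wgbs$pos, wgbs$strand, sep = ":")
  if (is.null(map)) {
    probe_key <- names(array)
    probe_id <- names(array)
  } else {
    stopifnot(all(c("probe_id", "chrom", "pos", "strand") %in% names(map)))
    probe_key <- paste(map$chrom, map$pos, map$strand, sep = ":")
    probe_id <- map$probe_id
    array <- array[probe_id]
  }
  if (is.null(probe_key)) stop("'array' must be named")
  idx <- match(probe_key, site_key)
  keep <- !is.na(idx) & !is.na(array)
  cov <- wgbs$coverage[idx[keep]]
  in_range <- cov >= min_cov & cov <= max_cov
  out <- data.frame(probe_id = probe_id[keep][in_range],
                    x = as.numeric(array[keep][in_range]),
                    y = wgbs$level[idx[keep]][in_range],
                    coverage = cov[in_range],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("no loci survive the coverage filter")
  out
}

#' Accuracy correlation between array and gold-standard levels
#'
#' Pearson product-moment correlation between paired array (`x`) and WGBS
#' (`y`) methylation levels.
#'
#' @param pairs `data.frame` with columns `x` and `y` (>= 3 rows).
#' @return Pearson r in \[-1, 1\].
#' @export
accuracy_correlation <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (stats::sd(pairs$x) == 0 || stats::sd(pairs$y) == 0)
    stop("zero variance in one coordinate")
  stats::cor(pairs$x, pairs$y, method = "pearson")
}

#' Fit the linear model and derive the reportable range
#'
#' Ordinary least squares of the gold-standard level on the array level,
#' `y = a + b x + e`. The reportable-range cut-offs are the array values at
#' which the fitted line reaches 0 and 1, clipped to \[0, 1\]. Optionally
#' iterates: refits restricted to pairs with `x` inside the current
#' `[R_low, R_high]` until the cut-offs move by less than `tol`, trimming
#' any non-linear tails outside the current linear portion.
#'
#' @param pairs `data.frame` with columns `x` and `y` (>= 3 rows).
#' @param iterate If `TRUE`, refit restricted to the current range until
#'   convergence (default `FALSE`: single pass).
#' @param tol Convergence tolerance on the cut-offs for the iterative mode.
#' @param max_iter Iteration cap.
#' @return An object of class `reportable_fit`: list with `a`, `b`,
#'   `adj_r2`, `n`, `R_low`, `R_high`, and `iterations`.
#' @export
fit_reportable_range <- function(pairs, iterate = FALSE, tol = 1e-4,
                                 max_iter = 20) {
  fit_once <- function(d) {
    if (nrow(d) < 3) stop("need at least 3 pairs to fit")
    fit <- stats::lm(y ~ x, data = d)
    a <- unname(stats::coef(fit)[1])
    b <- unname(stats::coef(fit)[2])
    if (is.na(b) || b <= 0)
      stop("fitted slope is not positive; reportable range undefined")
    list(a = a, b = b,
         adj_r2 = summary(fit)$adj.r.squared,
         n = nrow(d),
         R_low = max(0, -a / b),
         R_high = min(1, (1 - a) / b))
  }
  res <- fit_once(pairs)
  iters <- 1L
  if (iterate) {
    repeat {
      kept <- pairs[pairs$x >= res$R_low & pairs$x <= res$R_high, ,
                    drop = FALSE]
      nxt <- fit_once(kept)
      moved <- max(abs(nxt$R_low - res$R_low), abs(nxt$R_high - res$R_high))
      res <- nxt
      iters <- iters + 1L
      if (moved < tol || iters >= max_iter) break
    }
  }
  res$iterations <- iters
  class(res) <- "reportable_fit"
  res
}

#' @export
print.reportable_fit <- function(x, ...) {
  cat(sprintf(
    "Linear fit y = %.4f + %.4f x (n = %d, adj R^2 = %.3f)\n",
    x$a, x$b, x$n, x$adj_r2))
  cat(sprintf("Reportable range: [%.3f, %.3f]\n", x$R_low, x$R_high))
  invisible(x)
}

#' Aggregate per-sample reportable ranges
#'
#' The overall reportable range is the largest interval common to every
#' sample: the maximum of the per-sample lower cut-offs and the minimum of
#' the upper cut-offs.
#'
#' @param fits List of `reportable_fit` objects, or a `data.frame`/list
#'   with elements `R_low` and `R_high`.
#' @return Numeric `c(low, high)`.
#' @export
aggregate_reportable_range <- function(fits) {
  if (length(fits) == 0) stop("need at least one fit")
  if (is.list(fits) && !is.null(fits$R_low)) {
    lows <- fits$R_low
    highs <- fits$R_high
  } else {
    lows <- vapply(fits, function(f) f$R_low, numeric(1))
    highs <- vapply(fits, function(f) f$R_high, numeric(1))
  }
  low <- max(lows)
  high <- min(highs)
  if (low > high)
    stop(sprintf("per-sample ranges do not overlap (%.3f > %.3f)",
                 low, high))
  c(low, high)
}
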