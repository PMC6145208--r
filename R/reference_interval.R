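# Per-locus reference statistics from a known-normal population, and
# classification of where (if anywhere) aberrant methylation is detectable.

#' Build per-locus reference intervals from a reference population
#'
#' For each locus, computes the order statistics (min, quartiles, max) and
#' the empirical 95% interval — the 2.5th and 97.5th percentiles of the
#' reference-population methylation levels. Quantiles use linear
#' interpolation between order statistics at position `(n - 1) * p`
#' (`stats::quantile` type 7). Missing values are excluded per locus
#' (available-case n); loci with fewer than 2 non-missing values are
#' emitted with all statistics `NA` and `n < 2`.
#'
#' @param reference A beta matrix of the reference population (loci x
#'   samples).
#' @return A `data.frame` with columns `locus_id`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `lower`, `upper`, and `detectability`
#'   (initialized `NA`; see [classify_detectability()]).
#' @export
build_reference <- function(reference) {
  reference <- beta_matrix(reference)
  if (nrow(reference) == 0 || ncol(reference) == 0)
    stop("empty reference matrix")
  probs <- c(0, 0.25, 0.5, 0.75, 1, 0.025, 0.975)
  qs <- t(apply(reference, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) rep(NA_real_, 8)
    else c(stats::quantile(x, probs, type = 7, names = FALSE), length(x))
  }))
  out <- data.frame(
    locus_id = rownames(reference),
    n = ifelse(is.na(qs[, 8]),
               rowSums(!is.na(reference)), qs[, 8]),
    min = qs[, 1], q1 = qs[, 2], median = qs[, 3], q3 = qs[, 4],
    max = qs[, 5], lower = qs[, 6], upper = qs[, 7],
    detectability = NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize the interquartile-range distribution of a reference table
#'
#' Computes the per-locus IQR (`q3 - q1`), its histogram mode, and the
#' fraction of 95% intervals (`upper - lower`) narrower than a given width.
#' In a tight reference population the IQR distribution peaks near 0.03 and
#' most 95% intervals are narrower than 0.1.
#'
#' @param table Reference interval table from [build_reference()].
#' @param bin_width Histogram bin width for locating the IQR mode
#'   (default 0.005).
#' @param ci_width Width threshold for the 95%-interval summary
#'   (default 0.1).
#' @return A list with `iqr` (per-locus values), `mode` (midpoint of the
#'   modal histogram bin), `breaks`, `counts`, and `frac_ci_below`
#'   (fraction of loci with `upper - lower < ci_width`).
#' @export
summarize_iqr <- function(table, bin_width = 0.005, ci_width = 0.1) {
  if (nrow(table) == 0) stop("empty reference table")
  iqr <- table$q3 - table$q1
  iqr_ok <- iqr[!is.na(iqr)]
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  counts <- tabulate(findInterval(iqr_ok, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  modal_bin <- which.max(counts)
  width <- table$upper - table$lower
  list(iqr = iqr,
       mode = breaks[modal_bin] + bin_width / 2,
       breaks = breaks, counts = counts,
       frac_ci_below = mean(width < ci_width, na.rm = TRUE))
}

#' Classify per-locus detectability of aberrant methylation
#'
#' A locus can only show hypermethylation if a value `t` above its upper
#' reference bound is still attainable (`upper + t < 1`), and
#' hypomethylation only if a value `t` below its lower bound is both
#' positive and within the reportable range (`lower - t > max(0,
#' reportable_low)`). Inequalities are strict, so a bound exactly at the
#' boundary counts as blocked. Loci are labelled `both`, `hyper_only`,
#' `hypo_only`, or `undetectable`.
#'
#' @param table Reference interval table from [build_reference()].
#' @param t Aberrance threshold in (0, 1) (distance beyond the 95%
#'   interval required to call a level aberrant).
#' @param reportable_low Lower bound of the assay's reportable range.
#' @return The table with the `detectability` column filled (`NA` where the
#'   reference interval itself is `NA`).
#' @export
classify_detectability <- function(table, t, reportable_low = 0) {
  if (!(t > 0 && t < 1)) stop("t must be in (0, 1)")
  hyper_ok <- table$upper + t < 1
  hypo_ok <- table$lower - t > max(0, reportable_low)
  det <- ifelse(hyper_ok & hypo_ok, "both",
         ifelse(hyper_ok, "hyper_only",
         ifelse(hypo_ok, "hypo_only", "undetectable")))
  det[is.na(table$lower) | is.na(table$upper)] <- NA_character_
  table$detectability <- det
  table
}

#' Write a reference interval table as tab-delimited text
#'
#' @param table Reference interval table.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_reference_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a reference interval table written by [write_reference_table()]
#'
#' @param path Path to the TSV file.
#' @return A reference interval table `data.frame`.
#' @export
read_reference_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "n", "min", "q1", "median", "q3", "max",
            "lower", "upper", "detectability")
  if (!all(need %in% names(tab)))
    stop("reference table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$locus_id <- as.character(tab$locus_id)
  tab
}
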