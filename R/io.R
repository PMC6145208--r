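# Table readers/writers for the three external formats the pipeline touches:
# beta-value matrices, methcounts-style WGBS site tables, and probe intensity
# tables. All readers validate strictly and refuse to coerce silently.

#' Construct and validate a beta-value matrix
#'
#' A beta matrix stores per-CpG methylation levels (the fraction of cells
#' methylated at a locus, in \[0, 1\]) as a plain numeric matrix with loci in
#' rows and samples in columns. Missing measurements are `NA`; downstream
#' operations exclude them rather than treating them as zero.
#'
#' @param values Numeric matrix of methylation levels.
#' @param locus_ids Character vector of unique locus (probe) identifiers;
#'   defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return A validated numeric matrix with `locus_ids` as rownames and
#'   `sample_ids` as colnames.
#' @examples
#' beta_matrix(matrix(0.5, 3, 2), paste0("cg", 1:3), c("s1", "s2"))
#' @export
beta_matrix <- function(values, locus_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(locus_ids))
    locus_ids <- if (nrow(values) == 0) character(0) else
      stop("locus identifiers are required")
  if (is.null(sample_ids))
    sample_ids <- if (ncol(values) == 0) character(0) else
      stop("sample identifiers are required")
  locus_ids <- as.character(locus_ids)
  sample_ids <- as.character(sample_ids)
  if (length(locus_ids) != nrow(values))
    stop("length(locus_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "beta value outside [0,1] at locus '%s', sample '%s' (value %g)",
      locus_ids[bad[1, 1]], sample_ids[bad[1, 2]],
      values[bad[1, 1], bad[1, 2]]))
  dimnames(values) <- list(locus_ids, sample_ids)
  values
}

#' Read a beta-value matrix from tab-delimited text
#'
#' Expects a header row `locus_id<TAB>sample1<TAB>...` followed by one row
#' per locus. Values must lie in \[0, 1\]; missing cells are the literal
#' token `NA`. Decimal point only, no locale handling.
#'
#' @param path Path to a TSV file.
#' @return A validated beta matrix (see [beta_matrix()]).
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L || header[1] != "locus_id")
    stop("malformed beta matrix header: first column must be 'locus_id'")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  sample_ids <- colnames(raw)[-1]
  locus_ids <- raw[[1]]
  if (ncol(raw) == 1L) {
    vals <- matrix(numeric(0), nrow = nrow(raw), ncol = 0)
  } else if (nrow(raw) == 0L) {
    vals <- matrix(numeric(0), nrow = 0, ncol = length(sample_ids))
  } else {
    cells <- as.matrix(raw[, -1, drop = FALSE])
    suppressWarnings(vals <- matrix(as.numeric(cells), nrow = nrow(raw)))
    silent_na <- which(is.na(vals) & !is.na(cells) &
                         !(cells %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(silent_na) > 0)
      stop(sprintf("non-numeric beta value '%s' at locus '%s', sample '%s'",
                   cells[silent_na[1, 1], silent_na[1, 2]],
                   locus_ids[silent_na[1, 1]], sample_ids[silent_na[1, 2]]))
  }
  beta_matrix(vals, locus_ids, sample_ids)
}

#' Write a beta-value matrix as tab-delimited text
#'
#' Values are serialized with 15 significant digits so that a
#' write-then-read roundtrip reproduces the matrix exactly at double
#' precision for all practical purposes. `NA` cells are written as the
#' sentinel token `NA`.
#'
#' @param matrix A beta matrix (validated on the way out).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(matrix, path) {
  m <- beta_matrix(matrix)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("locus_id", colnames(m)), collapse = "\t"), con)
  if (nrow(m) > 0) {
    body <- apply(m, 1:2, function(v)
      if (is.na(v)) "NA" else sprintf("%.15g", v))
    body <- matrix(body, nrow = nrow(m))
    writeLines(paste(rownames(m),
                     apply(body, 1, paste, collapse = "\t"),
                     sep = if (ncol(m) > 0) "\t" else ""), con)
  }
  invisible(path)
}

#' Read a per-site WGBS methylation table (methcounts-style)
#'
#' Six whitespace-delimited columns, no header: chromosome, 0-based
#' position, strand, site context, methylation level in \[0, 1\], and read
#' coverage (non-negative integer). `(chrom, pos, strand)` triples must be
#' unique.
#'
#' @param path Path to a methcounts-style text file.
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `context`,
#'   `level`, `coverage`.
#' @export
read_wgbs_sites <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) != 6L)
    stop("WGBS site file must have exactly 6 columns, found ", ncol(raw))
  names(raw) <- c("chrom", "pos", "strand", "context", "level", "coverage")
  suppressWarnings({
    pos <- as.integer(raw$pos)
    level <- as.numeric(raw$level)
    coverage <- as.integer(raw$coverage)
  })
  if (anyNA(pos) || any(pos < 0))
    stop("WGBS positions must be non-negative integers (0-based)")
  if (!all(raw$strand %in% c("+", "-")))
    stop("WGBS strand must be '+' or '-'")
  if (anyNA(level) || any(level < 0 | level > 1))
    stop("WGBS methylation level outside [0,1] at line ",
         which(is.na(level) | level < 0 | level > 1)[1])
  if (anyNA(coverage) || any(coverage < 0))
    stop("WGBS coverage must be a non-negative integer at line ",
         which(is.na(coverage) | coverage < 0)[1])
  key <- paste(raw$chrom, pos, raw$strand)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, strand) site: ", key[duplicated(key)][1])
  data.frame(chrom = raw$chrom, pos = pos, strand = raw$strand,
             context = raw$context, level = level, coverage = coverage,
             stringsAsFactors = FALSE)
}

#' Write a per-site WGBS methylation table (methcounts-style)
#'
#' @param sites A data.frame as returned by [read_wgbs_sites()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_wgbs_sites <- function(sites, path) {
  stopifnot(all(c("chrom", "pos", "strand", "context", "level",
                  "coverage") %in% names(sites)))
  lines <- sprintf("%s\t%d\t%s\t%s\t%.15g\t%d",
                   sites$chrom, as.integer(sites$pos), sites$strand,
                   sites$context, sites$level, as.integer(sites$coverage))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe intensity table
#'
#' Tab-delimited with header `probe_id<TAB>M<TAB>U<TAB>is_background_control`
#' (booleans encoded 0/1). `M` and `U` are the methylated and unmethylated
#' fluorescence intensities (arbitrary units, non-negative). Detection
#' p-value computation requires background-control rows; their absence is
#' reported here as a warning and escalated to an error by
#' [detection_pvalues()].
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with columns `probe_id`, `M`, `U`,
#'   `is_background_control` (logical).
#' @export
read_intensity_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "M", "U", "is_background_control")
  if (!identical(names(raw), need))
    stop("intensity table header must be: ", paste(need, collapse = ", "))
  tab <- data.frame(probe_id = as.character(raw$probe_id),
                    M = as.numeric(raw$M), U = as.numeric(raw$U),
                    is_background_control =
                      as.logical(as.integer(raw$is_background_control)),
                    stringsAsFactors = FALSE)
  validate_intensity_table(tab)
}

validate_intensity_table <- function(tab) {
  if (anyNA(tab$M) || anyNA(tab$U) || any(tab$M < 0) || any(tab$U < 0)) {
    i <- which(is.na(tab$M) | is.na(tab$U) | tab$M < 0 | tab$U < 0)[1]
    stop("negative or missing intensity for probe '", tab$probe_id[i], "'")
  }
  if (anyNA(tab$is_background_control))
    stop("is_background_control must be 0/1")
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe id: ", tab$probe_id[duplicated(tab$probe_id)][1])
  if (!any(tab$is_background_control))
    warning("intensity table has no background-control rows; ",
            "detection p-values will not be computable")
  tab
}

#' Write a probe intensity table
#'
#' @param tab Intensity table as returned by [read_intensity_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_intensity_table <- function(tab, path) {
  stopifnot(all(c("probe_id", "M", "U", "is_background_control")
                %in% names(tab)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("probe_id\tM\tU\tis_background_control", con)
  writeLines(sprintf("%s\t%.15g\t%.15g\t%d", tab$probe_id, tab$M, tab$U,
                     as.integer(tab$is_background_control)), con)
  invisible(path)
}
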