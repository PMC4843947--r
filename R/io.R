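# On-disk artifacts.  All matrices are plain delimited text without headers;
# region order is positional and shared across a subject's files.  The cohort
# table is a delimited file with a header row and subject_id as join key.

read_delim_matrix <- function(path, delimiter = c("auto", "whitespace", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  sep <- switch(delimiter,
                auto = if (grepl(",", readLines(path, n = 1L))) "," else "",
                whitespace = "", tab = "\t", comma = ",")
  df <- tryCatch(
    read.table(path, sep = sep, header = FALSE, colClasses = "numeric",
               strip.white = TRUE),
    error = function(e) abort_format(sprintf("cannot parse %s as numeric: %s",
                                             path, conditionMessage(e))))
  m <- as.matrix(df)
  dimnames(m) <- NULL
  m
}

#' Read a streamline-count matrix
#'
#' Parses a whitespace-, tab- or comma-delimited text file holding an
#' N x N matrix of streamline counts between parcellation regions and
#' validates the structural-matrix contract: square, nonnegative integer
#' entries, zero diagonal, exactly symmetric.
#'
#' @param path path to the delimited text file (no header).
#' @param delimiter `"auto"` (default; comma detected from the first line,
#'   anything else read as whitespace), `"whitespace"`, `"tab"` or `"comma"`.
#' @param n optional expected region count; mismatch is an error.
#' @return an N x N integer matrix with zero diagonal.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("0 3", "3 0"), f)
#' read_streamline_matrix(f)
read_streamline_matrix <- function(path, delimiter = "auto", n = NULL) {
  m <- read_delim_matrix(path, delimiter)
  check_square(m, sprintf("streamline matrix %s", path))
  if (!is.null(n) && nrow(m) != n) {
    abort_format(sprintf("%s: expected %d regions, found %d", path, n, nrow(m)))
  }
  validate_streamline_matrix(m, what = path)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

validate_streamline_matrix <- function(m, what = "streamline matrix") {
  check_square(m, what)
  if (anyNA(m) || any(!is.finite(m))) {
    abort_validation(sprintf("%s: non-finite entries", what))
  }
  if (any(m < 0)) abort_validation(sprintf("%s: negative streamline count", what))
  if (!is_wholenumber(m)) {
    abort_validation(sprintf("%s: non-integer streamline count", what))
  }
  if (any(diag(m) != 0)) abort_validation(sprintf("%s: nonzero diagonal", what))
  bad <- which(m != t(m), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort_validation(sprintf(
      "%s: asymmetric at pair (%d, %d): %g vs %g", what, i, j, m[i, j], m[j, i]))
  }
  invisible(m)
}

#' Read a regional time-series table
#'
#' Parses a T x N delimited table of preprocessed regional BOLD signals
#' (rows = time points, columns = regions, positional region order).
#'
#' @inheritParams read_streamline_matrix
#' @return a T x N numeric matrix, all entries finite, T >= 2.
#' @export
read_timeseries <- function(path, delimiter = "auto", n = NULL) {
  m <- read_delim_matrix(path, delimiter)
  if (anyNA(m) || any(!is.finite(m))) {
    abort_validation(sprintf("%s: time series contains NaN/Inf", path))
  }
  if (nrow(m) < 2) {
    abort_validation(sprintf("%s: need at least 2 time points, found %d",
                             path, nrow(m)))
  }
  if (!is.null(n) && ncol(m) != n) {
    abort_format(sprintf("%s: expected %d regions, found %d", path, n, ncol(m)))
  }
  dimnames(m) <- NULL
  m
}

#' Write a numeric matrix as delimited text
#'
#' Full double precision (17 significant digits), so write-then-read
#' round-trips reals to the last bit and integers exactly.
#'
#' @param m matrix.
#' @param path output path.
#' @param delimiter `"tab"`, `"comma"` or `"whitespace"` (single space).
#' @export
write_matrix <- function(m, path, delimiter = c("tab", "comma", "whitespace")) {
  delimiter <- match.arg(delimiter)
  sep <- switch(delimiter, tab = "\t", comma = ",", whitespace = " ")
  x <- if (is.integer(m) || is_wholenumber(m)) {
    format(m, scientific = FALSE, trim = TRUE)
  } else {
    format(m, digits = 17, trim = TRUE)
  }
  lines <- apply(matrix(x, nrow = nrow(m)), 1, paste, collapse = sep)
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort metadata table
#'
#' The cohort table is a comma- or tab-delimited file with a header row and
#' one row per subject: `subject_id`, `group` (patient/control), `age`
#' (years), `sex` (M/F), `dose` (chlorpromazine-equivalent mg/day, 0 for
#' controls), `duration` (illness duration in years; empty for controls),
#' `symptom_score` (total SSPI; empty for controls).  Extra columns (for
#' example matched-control indicator columns) are kept.
#'
#' @param path file path.
#' @return a tibble, one row per subject.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("cohort file not found: %s", path))
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else "\t"
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  validate_cohort(tibble::as_tibble(df))
}

validate_cohort <- function(cohort) {
  need <- c("subject_id", "group", "age", "sex", "dose")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort_format(sprintf("cohort table missing columns: %s",
                         paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(cohort$subject_id)) {
    abort_validation("cohort: duplicated subject_id")
  }
  if (!all(cohort$group %in% c("patient", "control"))) {
    abort_validation("cohort: group must be 'patient' or 'control'")
  }
  if (!all(cohort$sex %in% c("M", "F"))) {
    abort_validation("cohort: sex must be 'M' or 'F'")
  }
  if (any(cohort$age <= 0)) abort_validation("cohort: age must be > 0")
  if (any(cohort$dose < 0)) abort_validation("cohort: dose must be >= 0")
  if ("duration" %in% names(cohort) &&
      any(cohort$duration < 0, na.rm = TRUE)) {
    abort_validation("cohort: duration must be >= 0")
  }
  cohort
}

#' @rdname read_cohort
#' @param cohort cohort tibble.
#' @export
write_cohort_table <- function(cohort, path) {
  write.table(cohort, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Read a cohort directory produced by `write_cohort()` or the CLI
#'
#' Expects `cohort.csv` plus per-subject `streamlines_<id>.tsv` and
#' `timeseries_<id>.tsv` files.
#'
#' @param dir directory path.
#' @return an `fce_cohort` object: list with `cohort` (tibble),
#'   `streamlines` and `timeseries` (named lists of matrices).
#' @export
read_cohort_dir <- function(dir) {
  cohort <- read_cohort(file.path(dir, "cohort.csv"))
  ids <- cohort$subject_id
  sl <- ts <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    fs <- file.path(dir, sprintf("streamlines_%s.tsv", id))
    ft <- file.path(dir, sprintf("timeseries_%s.tsv", id))
    if (!file.exists(fs)) abort_format(sprintf("missing streamline file: %s", fs))
    if (!file.exists(ft)) abort_format(sprintf("missing time-series file: %s", ft))
    sl[[id]] <- read_streamline_matrix(fs)
    ts[[id]] <- read_timeseries(ft)
  }
  new_fce_cohort(cohort, sl, ts)
}

new_fce_cohort <- function(cohort, streamlines, timeseries, truth = NULL) {
  structure(list(cohort = cohort, streamlines = streamlines,
                 timeseries = timeseries, truth = truth),
            class = "fce_cohort")
}

#' @export
print.fce_cohort <- function(x, ...) {
  n <- nrow(x$cohort)
  np <- sum(x$cohort$group == "patient")
  nr <- if (length(x$streamlines)) nrow(x$streamlines[[1]]) else NA
  cat(sprintf("<fce_cohort> %d subjects (%d patients, %d controls), %s regions\n",
              n, np, n - np, nr))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

# Plain-text run log: one "key: value" line per parameter, then messages.
write_run_log <- function(path, params, messages = character()) {
  lines <- c(sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("%s: %s", names(params),
                     vapply(params, function(v)
                       paste(format(v), collapse = ","), character(1))),
             messages)
  writeLines(lines, path)
  invisible(path)
}
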