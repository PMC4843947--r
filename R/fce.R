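# Functional connectivity entropy (FCE).
#
# FCE quantifies the spatial unpredictability of connectivity strength: the
# Shannon entropy of the histogram of pairwise correlation values over a set
# of links.  A brain whose links all share one strength has FCE 0; a brain
# whose link strengths spread evenly over the admissible range attains the
# log of the bin count.  Computed whole-brain and within each structural
# path class.

#' Histogram bin specification
#'
#' Equal-width bins over a fixed range; bins are left-closed/right-open
#' except the last, which is closed so the upper limit is included.
#'
#' @param n_bins integer >= 2.
#' @param range numeric `c(lo, hi)`, lo < hi.
#' @return a list of class `bin_spec`.
#' @export
bin_spec <- function(n_bins = 100L, range = c(-1, 1)) {
  if (!is_wholenumber(n_bins) || n_bins < 2) {
    abort_parameter("`n_bins` must be an integer >= 2")
  }
  if (length(range) != 2 || !is.numeric(range) || range[1] >= range[2]) {
    abort_parameter("`range` must be c(lo, hi) with lo < hi")
  }
  structure(list(n_bins = as.integer(n_bins), range = as.numeric(range)),
            class = "bin_spec")
}

#' Bin connectivity values into a probability vector
#'
#' @param values numeric vector of connectivity values, all inside the bin
#'   range; values outside are an error, never silently clamped.
#' @param bins a [bin_spec()].
#' @return numeric vector of length `n_bins`, nonnegative, summing to 1.
#' @export
#' @examples
#' fc_histogram(c(-0.9, -0.1, 0.4, 0.9), bin_spec(4, c(-1, 1)))
fc_histogram <- function(values, bins = bin_spec()) {
  if (!inherits(bins, "bin_spec")) abort_parameter("`bins` must be a bin_spec")
  if (length(values) == 0) abort_validation("no values to bin")
  if (anyNA(values) || any(!is.finite(values))) {
    abort_validation("non-finite connectivity value")
  }
  lo <- bins$range[1]; hi <- bins$range[2]
  out <- values < lo | values > hi
  if (any(out)) {
    abort_validation(sprintf("value %g outside bin range [%g, %g]",
                             values[which(out)[1]], lo, hi))
  }
  width <- (hi - lo) / bins$n_bins
  idx <- floor((values - lo) / width) + 1
  idx[idx > bins$n_bins] <- bins$n_bins  # hi itself falls in the last bin
  tabulate(idx, nbins = bins$n_bins) / length(values)
}

#' Shannon entropy of a probability vector
#'
#' `H = -sum(p * log(p, base))`, zero-mass bins contributing nothing.
#'
#' @param p nonnegative numeric vector summing to 1 (tolerance 1e-9).
#' @param log_base logarithm base; 2 (default) gives bits.
#' @return entropy in `0 .. log(length(p), log_base)`.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.25, 0.25))  # 1.5 bits
shannon_entropy <- function(p, log_base = 2) {
  if (any(p < 0)) abort_validation("negative probability mass")
  if (abs(sum(p) - 1) > 1e-9) {
    abort_validation(sprintf("probabilities sum to %.12f, not 1", sum(p)))
  }
  nz <- p[p > 0]
  -sum(nz * log(nz, base = log_base))
}

# Miller-Madow bias-corrected entropy: plug-in + (K-1)/(2N) nats, with K the
# number of occupied bins and N the sample count, converted to the log base.
miller_madow_entropy <- function(p, n, log_base = 2) {
  shannon_entropy(p, log_base) + (sum(p > 0) - 1) / (2 * n * log(log_base))
}

#' FCE per structural path stratum
#'
#' Computes the entropy of the connectivity distribution for the whole
#' brain (all off-diagonal pairs, whatever their structural class) and for
#' each path-class stratum.  Disconnected pairs enter only the whole-brain
#' stratum.  Strata with fewer than two links get `entropy_bits = NA` and
#' `undefined = TRUE`; they are excluded from group statistics downstream
#' rather than contributing a degenerate zero.
#'
#' @param fc N x N (transformed) connectivity matrix.
#' @param pcm `path_class_matrix` for the same regions.
#' @param bins a [bin_spec()].
#' @param higher_order_policy `"separate"` or `"merge_into_tertiary"`.
#' @param estimator `"plugin"` or `"miller_madow"`.
#' @param log_base entropy base (2 = bits).
#' @param subject_id optional id recorded in the output.
#' @return tibble: `subject_id`, `stratum`, `entropy_bits`, `n_links`,
#'   `n_bins`, `bin_lo`, `bin_hi`, `transform`, `estimator`, `undefined`.
#' @export
fce_by_stratum <- function(fc, pcm, bins = bin_spec(),
                           higher_order_policy = c("separate",
                                                   "merge_into_tertiary"),
                           estimator = c("plugin", "miller_madow"),
                           log_base = 2, subject_id = NA_character_) {
  higher_order_policy <- match.arg(higher_order_policy)
  estimator <- match.arg(estimator)
  if (nrow(fc) != nrow(pcm)) {
    abort_validation("fc and path-class matrices differ in region count")
  }
  vals <- upper_pairs(unclass(fc))
  codes <- upper_pairs(unclass(pcm))
  if (higher_order_policy == "merge_into_tertiary") {
    codes[codes == PATH_CLASS_CODES[["higher"]]] <- PATH_CLASS_CODES[["tertiary"]]
  }
  strata <- c("whole_brain", "primary", "secondary", "tertiary",
              if (higher_order_policy == "separate") "higher")
  h <- n <- numeric(length(strata))
  for (k in seq_along(strata)) {
    v <- if (strata[k] == "whole_brain") vals
         else vals[codes == PATH_CLASS_CODES[[strata[k]]]]
    n[k] <- length(v)
    h[k] <- if (n[k] < 2) NA_real_ else {
      p <- fc_histogram(v, bins)
      if (estimator == "plugin") shannon_entropy(p, log_base)
      else miller_madow_entropy(p, n[k], log_base)
    }
  }
  tibble::tibble(subject_id = subject_id, stratum = strata,
                 entropy_bits = h, n_links = as.integer(n),
                 undefined = n < 2,
                 n_bins = bins$n_bins, bin_lo = bins$range[1],
                 bin_hi = bins$range[2],
                 transform = attr(fc, "transform") %||% NA_character_,
                 estimator = estimator)
}

#' FCE table for a whole cohort
#'
#' Runs classification (at the configured streamline threshold), Pearson
#' connectivity, the configured value transform and stratified entropy for
#' every subject of a cohort, returning one tidy table.
#'
#' @param cohort_data an `fce_cohort` (from [simulate_cohort()] or
#'   [read_cohort_dir()]).
#' @param config an [fce_config()].
#' @return an `fce_table` tibble (one row per subject x stratum).
#' @export
compute_fce_cohort <- function(cohort_data, config = fce_config()) {
  stopifnot(inherits(cohort_data, "fce_cohort"))
  bins <- bin_spec(config$n_bins, config$bin_range)
  out <- purrr::map_dfr(cohort_data$cohort$subject_id, function(id) {
    adj <- binarize_streamlines(cohort_data$streamlines[[id]],
                                config$min_streamlines)
    pcm <- classify_paths(adj)
    fc <- transform_fc(pearson_fc(cohort_data$timeseries[[id]]),
                       config$fc_transform)
    fce_by_stratum(fc, pcm, bins,
                   higher_order_policy = config$higher_order_policy,
                   estimator = config$estimator,
                   log_base = config$log_base, subject_id = id)
  })
  class(out) <- c("fce_table", class(out))
  attr(out, "config") <- config
  out
}

#' Write an FCE table as CSV
#'
#' @param fce_table output of [compute_fce_cohort()] or [fce_by_stratum()].
#' @param path file path.
#' @export
write_fce_table <- function(fce_table, path) {
  write.table(fce_table, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_fce_table
#' @export
read_fce_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("FCE table not found: %s", path))
  df <- tibble::as_tibble(read.table(path, sep = ",", header = TRUE,
                                     stringsAsFactors = FALSE))
  class(df) <- c("fce_table", class(df))
  df
}
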