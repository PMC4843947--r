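#' Pipeline configuration
#'
#' Bundles the analysis choices that the path classification, entropy and
#' group-comparison steps share: the minimum streamline count treated as a
#' structural edge, the histogram bin scheme for the entropy, the value
#' transform applied to correlations before binning, the illness-duration
#' cutoff, and the treatment of path orders beyond tertiary.
#'
#' @param min_streamlines smallest streamline count that counts as a direct
#'   structural edge when binarizing a tractography matrix.  The sensitivity
#'   sweep runs 1--3; values outside that range are allowed with a warning.
#' @param n_bins number of equal-width histogram bins for the entropy.
#' @param bin_range numeric length-2, the value range spanned by the bins.
#'   The default `c(-1, 1)` covers raw correlations.
#' @param log_base base of the entropy logarithm (2 gives bits).
#' @param duration_cutoff illness-duration cutoff in years separating
#'   early-stage (`duration < cutoff`) from late-stage patients.
#' @param higher_order_policy `"separate"` keeps pairs at shortest path
#'   length >= 4 as their own `"higher"` stratum; `"merge_into_tertiary"`
#'   pools them with tertiary pairs.
#' @param fc_transform transform applied to the correlation matrix before
#'   binning: `"raw_r"` (identity, default), `"abs_r"` or `"fisher_z"`.
#'   With `"fisher_z"` choose a `bin_range` wide enough for the z values.
#' @param estimator `"plugin"` (maximum-likelihood histogram entropy) or
#'   `"miller_madow"` (adds the (K-1)/2N small-sample bias correction,
#'   relevant for small strata such as tertiary paths).
#' @param seed integer seed recorded with the run (used by subcommands that
#'   involve randomness).
#'
#' @return a list of class `fce_config`.
#' @export
#' @examples
#' fce_config(min_streamlines = 2, n_bins = 50)
fce_config <- function(min_streamlines = 1L,
                       n_bins = 100L,
                       bin_range = c(-1, 1),
                       log_base = 2,
                       duration_cutoff = 5,
                       higher_order_policy = c("separate", "merge_into_tertiary"),
                       fc_transform = c("raw_r", "abs_r", "fisher_z"),
                       estimator = c("plugin", "miller_madow"),
                       seed = NULL) {
  higher_order_policy <- match.arg(higher_order_policy)
  fc_transform <- match.arg(fc_transform)
  estimator <- match.arg(estimator)
  if (!is_wholenumber(min_streamlines) || min_streamlines < 1) {
    abort_parameter("`min_streamlines` must be an integer >= 1")
  }
  if (min_streamlines > 3) {
    warn(sprintf("min_streamlines = %d is outside the usual 1-3 range",
                 as.integer(min_streamlines)))
  }
  if (!is_wholenumber(n_bins) || n_bins < 2) {
    abort_parameter("`n_bins` must be an integer >= 2")
  }
  if (length(bin_range) != 2 || !is.numeric(bin_range) ||
      bin_range[1] >= bin_range[2]) {
    abort_parameter("`bin_range` must be c(lo, hi) with lo < hi")
  }
  if (!is.numeric(log_base) || log_base <= 1) {
    abort_parameter("`log_base` must be > 1")
  }
  if (!is.numeric(duration_cutoff) || duration_cutoff <= 0) {
    abort_parameter("`duration_cutoff` must be positive (years)")
  }
  structure(list(
    min_streamlines = as.integer(min_streamlines),
    n_bins = as.integer(n_bins),
    bin_range = as.numeric(bin_range),
    log_base = log_base,
    duration_cutoff = duration_cutoff,
    higher_order_policy = higher_order_policy,
    fc_transform = fc_transform,
    estimator = estimator,
    seed = if (!is.null(seed)) as.integer(seed)
  ), class = "fce_config")
}

#' @export
print.fce_config <- function(x, ...) {
  cat("<fce_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' Configurations are stored as flat YAML.  `write_config()` is used by the
#' pipeline to drop an effective-config copy beside every output so the
#' threshold and binning decisions of a run are always recoverable.
#'
#' @param path file path.
#' @return `read_config()` returns an `fce_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(fce_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_format(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(fce_config, raw)
}

#' @param config an `fce_config` (or any named list of scalars).
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}
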