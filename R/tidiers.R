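# broom-style accessors for fitted result objects.

#' Tidy a group-comparison report
#'
#' @param x an `fce_report` from [run_full_comparison()].
#' @param ... unused.
#' @return the comparison tibble: one row per duration stratum x FCE
#'   stratum with means, t, p, Cohen's d, direction and symptom
#'   correlation.
#' @export
tidy.fce_report <- function(x, ...) x$comparisons

#' @rdname tidy.fce_report
#' @return `glance()` returns a one-row tibble: number of tests run (no
#'   multiplicity correction is applied; correct externally if desired),
#'   streamline threshold, bin scheme and transform.
#' @export
glance.fce_report <- function(x, ...) {
  tibble::tibble(n_tests = x$n_tests,
                 min_streamlines = x$config$min_streamlines,
                 n_bins = x$config$n_bins,
                 fc_transform = x$config$fc_transform,
                 estimator = x$config$estimator,
                 duration_cutoff = x$config$duration_cutoff)
}

#' Tidy a threshold sweep
#'
#' @param x a `threshold_sweep` from [threshold_sensitivity()].
#' @param ... unused.
#' @return comparisons of every swept threshold stacked with a
#'   `min_streamlines` column.
#' @export
tidy.threshold_sweep <- function(x, ...) {
  purrr::map_dfr(names(x$per_threshold), function(k) {
    dplyr::mutate(x$per_threshold[[k]]$comparisons,
                  min_streamlines = as.integer(k), .before = 1)
  })
}

#' @rdname tidy.threshold_sweep
#' @export
glance.threshold_sweep <- function(x, ...) {
  tibble::tibble(n_thresholds = length(x$thresholds),
                 mean_cross_threshold_agreement = mean(x$agreement$mean_agreement),
                 min_cross_threshold_agreement = min(x$agreement$min_agreement))
}
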