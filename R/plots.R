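# Plotting.  All plot functions return ggplot objects.

#' Plot effect sizes from a comparison report
#'
#' Cohen's d per FCE stratum and duration stratum, signed by the direction
#' of the patient-control difference (positive = patients higher).
#'
#' @param object an `fce_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fce_report <- function(object, ...) {
  d <- dplyr::filter(object$comparisons, !.data$flagged)
  d <- dplyr::mutate(d, signed_d = .data$direction * .data$cohen_d,
                     stratum = factor(.data$stratum,
                                      levels = c("whole_brain", "primary",
                                                 "secondary", "tertiary",
                                                 "higher")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stratum, y = .data$signed_d,
                                  fill = .data$duration_stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "FCE stratum", y = "signed Cohen's d (patient - control)",
                  fill = "patients") +
    ggplot2::theme_minimal()
}

#' Plot per-subject FCE distributions
#'
#' @param object an `fce_table` from [compute_fce_cohort()].
#' @param cohort optional cohort tibble; if given, boxes are split by group.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fce_table <- function(object, cohort = NULL, ...) {
  d <- dplyr::filter(object, !.data$undefined)
  if (!is.null(cohort)) {
    d <- dplyr::inner_join(d, dplyr::select(cohort, "subject_id", "group"),
                           by = "subject_id")
    aes <- ggplot2::aes(x = .data$stratum, y = .data$entropy_bits,
                        fill = .data$group)
  } else {
    aes <- ggplot2::aes(x = .data$stratum, y = .data$entropy_bits)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "stratum", y = "FCE (bits)") +
    ggplot2::theme_minimal()
}

#' Histogram of connectivity values faceted by path class
#'
#' Shows the binned distributions whose entropies the FCE summarizes.
#'
#' @param fc connectivity matrix.
#' @param pcm `path_class_matrix`.
#' @param bins a [bin_spec()].
#' @return a ggplot.
#' @export
plot_fc_strata <- function(fc, pcm, bins = bin_spec()) {
  vals <- upper_pairs(unclass(fc))
  lab <- path_class_label(upper_pairs(unclass(pcm)))
  d <- tibble::tibble(fc = vals,
                      class = factor(lab, levels = PATH_CLASS_ORDER))
  d <- dplyr::filter(d, !is.na(.data$class))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fc)) +
    ggplot2::geom_histogram(breaks = seq(bins$range[1], bins$range[2],
                                         length.out = bins$n_bins + 1)) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "functional connectivity", y = "pairs") +
    ggplot2::theme_minimal()
}
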