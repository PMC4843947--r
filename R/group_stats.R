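# Group statistics: covariate residualization, two-sample comparison with
# Cohen's d, symptom correlation, duration stratification and the streamline
# threshold sensitivity sweep.

#' Residualize values against nuisance covariates
#'
#' Ordinary least squares of the values on age, sex and antipsychotic dose
#' (or any supplied design), returning residuals with the grand mean added
#' back so group means stay on the original scale.  Covariate columns with
#' zero variance (for example dose in a control-only subset) carry no
#' information beyond the intercept and are dropped; genuinely collinear
#' designs are an error.
#'
#' @param values numeric vector, one per subject.
#' @param covariates data frame or matrix of numeric covariate columns
#'   (same row order as `values`).
#' @return numeric residuals + grand mean; orthogonal to every retained
#'   covariate column.
#' @export
#' @examples
#' age <- c(20, 30, 40, 50)
#' residualize(2 * age + 1, data.frame(age = age))  # all equal to the mean
residualize <- function(values, covariates) {
  X <- as.matrix(covariates)
  if (!is.numeric(X)) abort_validation("covariates must be numeric")
  if (nrow(X) != length(values)) {
    abort_validation("values and covariates differ in length")
  }
  keep <- apply(X, 2, function(col) var(col) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) > 0) {
    if (length(values) < ncol(X) + 3) {
      abort_validation("need at least two more subjects than covariates")
    }
    Xi <- cbind(1, X)
    qrX <- qr(Xi)
    if (qrX$rank < ncol(Xi)) {
      dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(Xi))] - 1]
      abort_validation(sprintf("collinear covariate columns: %s",
                               paste(dropped, collapse = ", ")))
    }
    fit <- lm(values ~ X)
    unname(resid(fit)) + mean(values)
  } else {
    values
  }
}

# 0/1 coding of sex for the design matrix (M = 0, F = 1)
sex_code <- function(sex) as.numeric(sex == "F")

#' Two-sample comparison with Cohen's d
#'
#' Student's pooled-variance t test (Welch by flag), two-tailed p, and
#' Cohen's d as the absolute mean difference over the pooled (n-1) standard
#' deviation.  The direction of the difference is carried separately as the
#' sign of `mean_patient - mean_control`.
#'
#' @param x control values.
#' @param y patient values.
#' @param var_equal pooled-variance Student t if `TRUE` (default), Welch
#'   otherwise.
#' @return one-row tibble: `n_control`, `n_patient`, `mean_control`,
#'   `mean_patient`, `direction`, `t_stat`, `p_value`, `cohen_d`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(2, 3, 4))  # d = 1
compare_groups <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    abort_validation("each group needs at least 2 subjects")
  }
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) abort_validation("zero pooled variance")
  tt <- t.test(y, x, var.equal = var_equal)
  tibble::tibble(
    n_control = length(x), n_patient = length(y),
    mean_control = mean(x), mean_patient = mean(y),
    direction = sign(mean(y) - mean(x)),
    t_stat = unname(tt$statistic), p_value = tt$p.value,
    cohen_d = abs(mean(y) - mean(x)) / sqrt(sp2))
}

#' Pearson correlation of FCE with symptom burden
#'
#' @param fce patient FCE values.
#' @param sspi matching total SSPI symptom scores.
#' @return one-row tibble: `n`, `r`, `p_value` (two-tailed, from the t
#'   transform of r with n - 2 degrees of freedom).
#' @export
correlate_with_symptoms <- function(fce, sspi) {
  ok <- is.finite(fce) & is.finite(sspi)
  fce <- fce[ok]; sspi <- sspi[ok]
  if (length(fce) < 3) abort_validation("need at least 3 patients with both values")
  if (sd(fce) == 0 || sd(sspi) == 0) abort_validation("constant input to correlation")
  ct <- cor.test(fce, sspi)
  tibble::tibble(n = length(fce), r = unname(ct$estimate),
                 p_value = ct$p.value)
}

#' Derive the illness-duration stratum
#'
#' Patients with `duration < cutoff` are early-stage, the rest late-stage;
#' controls get `NA`.
#'
#' @param cohort cohort tibble with `group` and `duration` columns.
#' @param cutoff years (default 5).
#' @return the cohort with a `duration_stratum` column.
#' @export
add_duration_stratum <- function(cohort, cutoff = 5) {
  dplyr::mutate(cohort, duration_stratum = dplyr::case_when(
    .data$group != "patient" ~ NA_character_,
    .data$duration < cutoff ~ "early",
    TRUE ~ "late"))
}

#' Full group comparison report
#'
#' For the pooled patient group and for each illness-duration stratum
#' (early / late) versus controls, and for each FCE stratum, residualizes
#' FCE against age, sex and dose across the compared subjects (pooled
#' design; dose is zero for controls), runs the two-sample comparison, and
#' correlates residualized patient FCE with the symptom score.
#'
#' @param fce_table tidy FCE table from [compute_fce_cohort()].
#' @param cohort cohort tibble (see [read_cohort()]).
#' @param config an [fce_config()]; supplies the duration cutoff.
#' @param control_subset optional named character vector mapping duration
#'   strata to logical cohort columns selecting the matched control subset,
#'   e.g. `c(early = "matched_early", late = "matched_late")`.  By default
#'   every control enters every comparison.
#' @param var_equal pooled-variance t (default) or Welch.
#' @param residualize_per_group residualize patients and controls in
#'   separate regressions instead of one pooled design.
#' @return an `fce_report`: list with `comparisons` (tibble), `n_tests`,
#'   `config`.
#' @export
run_full_comparison <- function(fce_table, cohort, config = fce_config(),
                                control_subset = NULL, var_equal = TRUE,
                                residualize_per_group = FALSE) {
  cohort <- add_duration_stratum(validate_cohort(cohort),
                                 config$duration_cutoff)
  dat <- dplyr::inner_join(fce_table, cohort, by = "subject_id")
  strata <- setdiff(unique(dat$stratum), character(0))
  groups <- list(all = c("early", "late"), early = "early", late = "late")

  rows <- purrr::map_dfr(names(groups), function(gname) {
    purrr::map_dfr(strata, function(s) {
      block <- dplyr::filter(dat, .data$stratum == s, !.data$undefined)
      pat <- dplyr::filter(block, .data$group == "patient",
                           .data$duration_stratum %in% groups[[gname]])
      ctl <- dplyr::filter(block, .data$group == "control")
      if (!is.null(control_subset) && gname %in% names(control_subset)) {
        keep <- cohort$subject_id[isTRUE_vec(cohort[[control_subset[[gname]]]])]
        ctl <- dplyr::filter(ctl, .data$subject_id %in% keep)
      }
      # too few subjects for the comparison or the covariate design
      if (nrow(pat) < 2 || nrow(ctl) < 2 || nrow(pat) + nrow(ctl) < 6) {
        return(tibble::tibble(duration_stratum = gname, stratum = s,
                              flagged = TRUE))
      }
      sub <- dplyr::bind_rows(ctl, pat)
      covs <- data.frame(age = sub$age, sex = sex_code(sub$sex),
                         dose = sub$dose)
      res <- if (residualize_per_group) {
        is_pat <- sub$group == "patient"
        r <- numeric(nrow(sub))
        r[!is_pat] <- residualize(sub$entropy_bits[!is_pat],
                                  covs[!is_pat, , drop = FALSE])
        r[is_pat] <- residualize(sub$entropy_bits[is_pat],
                                 covs[is_pat, , drop = FALSE])
        r
      } else {
        residualize(sub$entropy_bits, covs)
      }
      cmp <- compare_groups(res[sub$group == "control"],
                            res[sub$group == "patient"],
                            var_equal = var_equal)
      sy <- sub$symptom_score[sub$group == "patient"]
      cor_row <- if (sum(is.finite(sy)) >= 3 &&
                     sd(res[sub$group == "patient"][is.finite(sy)]) > 0) {
        correlate_with_symptoms(res[sub$group == "patient"], sy)
      } else {
        tibble::tibble(n = NA_integer_, r = NA_real_, p_value = NA_real_)
      }
      tibble::tibble(duration_stratum = gname, stratum = s, flagged = FALSE,
                     cmp,
                     r_symptom = cor_row$r, p_symptom = cor_row$p_value,
                     n_symptom = cor_row$n)
    })
  })
  structure(list(comparisons = rows,
                 n_tests = sum(!rows$flagged),
                 config = config),
            class = "fce_report")
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)

#' @export
print.fce_report <- function(x, ...) {
  cat(sprintf("<fce_report> %d comparisons (no multiplicity correction applied)\n",
              x$n_tests))
  print(x$comparisons, n = Inf)
  invisible(x)
}

#' Write a group-comparison report as CSV
#'
#' @param report an `fce_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  write.table(report$comparisons, path, sep = ",", row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}

#' Streamline-threshold sensitivity sweep
#'
#' Reruns classification, FCE and the group comparison at each minimum
#' streamline threshold, and summarizes how stable the pair classifications
#' are across thresholds (per-subject agreement fractions between every
#' threshold pair).
#'
#' @param cohort_data an `fce_cohort`.
#' @param config base [fce_config()]; `min_streamlines` is overridden by
#'   each swept value.
#' @param thresholds integer vector of thresholds (default 1:3).
#' @return a `threshold_sweep`: list with `per_threshold` (named list of
#'   `fce_report`s), `proportions` (tibble of class proportions per
#'   threshold, group consensus), `agreement` (tibble: threshold_a,
#'   threshold_b, mean/min per-subject agreement fraction).
#' @export
threshold_sensitivity <- function(cohort_data, config = fce_config(),
                                  thresholds = 1:3) {
  stopifnot(inherits(cohort_data, "fce_cohort"))
  ids <- cohort_data$cohort$subject_id
  pcms <- lapply(thresholds, function(k) {
    lapply(cohort_data$streamlines[ids], function(m) {
      classify_paths(binarize_streamlines(m, k))
    })
  })
  names(pcms) <- as.character(thresholds)

  reports <- lapply(thresholds, function(k) {
    cfg <- config
    cfg$min_streamlines <- as.integer(k)
    run_full_comparison(compute_fce_cohort(cohort_data, cfg),
                        cohort_data$cohort, cfg)
  })
  names(reports) <- as.character(thresholds)

  proportions <- purrr::map_dfr(as.character(thresholds), function(k) {
    cons <- consensus_path_class(pcms[[k]])
    dplyr::mutate(path_class_proportions(cons), min_streamlines = as.integer(k),
                  .before = 1)
  })

  pairs <- utils::combn(as.character(thresholds), 2, simplify = FALSE)
  agreement <- purrr::map_dfr(pairs, function(pr) {
    fr <- vapply(ids, function(id) {
      class_agreement(pcms[[pr[1]]][[id]], pcms[[pr[2]]][[id]])$fraction
    }, numeric(1))
    tibble::tibble(threshold_a = as.integer(pr[1]),
                   threshold_b = as.integer(pr[2]),
                   mean_agreement = mean(fr), min_agreement = min(fr))
  })

  structure(list(per_threshold = reports, proportions = proportions,
                 agreement = agreement, thresholds = thresholds),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> thresholds %s\n",
              paste(x$thresholds, collapse = ", ")))
  cat("cross-threshold classification agreement:\n")
  print(x$agreement)
  invisible(x)
}
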