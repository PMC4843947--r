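# Synthetic-cohort generator.
#
# Emulates the structure of a 90-region patient/control connectome study:
# per-subject structural networks whose unordered pairs split roughly
# 28% primary / 69% secondary / 3% tertiary, functional correlations whose
# mean decreases with path order, and group- and severity-dependent spread
# (the entropy handle) with linear age/sex/dose nuisance effects.  Every
# designed quantity is persisted as ground truth so recovery is testable.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the package targets: 90 regions,
#' 32 controls and 34 patients (17 early-stage, 17 late-stage), ten-minute
#' resting scans summarized as 240 time points, a structural network whose
#' primary-pair proportion is calibrated to 27.8%, class mean correlations
#' decreasing with path order, and designed per-class spread modifications
#' (early stage: secondary spread up, tertiary down; late stage: all down,
#' tertiary most) whose effect sizes fall in the large-d range the
#' whole-cohort comparisons are meant to detect.
#'
#' @param n_regions number of parcellation regions.
#' @param n_timepoints time points per subject.
#' @param n_control,n_early,n_late group sizes (early/late by illness
#'   duration around the 5-year cutoff).
#' @param target_primary calibration target for the proportion of primary
#'   (directly connected) pairs.
#' @param decay_shape exponent of the distance-decay edge model
#'   `p = exp(-(d / s)^shape)`.  The scale `s` is calibrated to the primary
#'   target; the shape sets how local the network is and therefore how the
#'   remaining pairs split between secondary and tertiary.  The default 2.5
#'   puts the split in the 69% / 3% regime.
#' @param count_mean,count_dispersion negative-binomial mean and size for
#'   streamline counts on present edges (floored at 1).
#' @param mu named class means of the target correlations
#'   (primary > secondary > tertiary required, all in (-1, 1)).
#' @param sigma named class spreads of the target correlations (the
#'   entropy handle; > 0).
#' @param group_sigma_mult named list (`control`, `early`, `late`) of
#'   per-class multiplicative spread modifications.
#' @param age_slope,sex_slope,dose_slope linear nuisance effects on
#'   log-spread per year of age (centered), for female sex, and per
#'   mg/day chlorpromazine-equivalent dose.
#' @param severity_coupling named list (`early`, `late`) of per-class
#'   slopes of log-spread on the latent severity (standard normal per
#'   patient); the same latent drives the symptom score, which makes
#'   FCE--symptom correlations of the configured sign recoverable.
#' @param subject_sigma_jitter SD of a per-subject log-spread perturbation
#'   shared across classes; sets realistic between-subject FCE variability.
#' @param sspi_mean,sspi_slope,sspi_noise symptom-score model:
#'   `sspi = mean + slope * severity + N(0, noise)`, floored at 0.
#' @param age_mean,age_sd,age_range,prop_male,dose_meanlog,dose_sdlog
#'   covariate distributions (age truncated normal; dose log-normal for
#'   patients, 0 for controls).
#' @param duration_cutoff years separating early from late stage.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 90L,
                       n_timepoints = 240L,
                       n_control = 32L,
                       n_early = 17L,
                       n_late = 17L,
                       target_primary = 0.278,
                       decay_shape = 2.5,
                       count_mean = 25,
                       count_dispersion = 0.8,
                       mu = c(primary = 0.32, secondary = 0.17,
                              tertiary = 0.06),
                       sigma = c(primary = 0.11, secondary = 0.095,
                                 tertiary = 0.075),
                       group_sigma_mult = list(
                         control = c(primary = 1, secondary = 1, tertiary = 1),
                         early = c(primary = 1, secondary = 1.35, tertiary = 0.60),
                         late = c(primary = 0.70, secondary = 0.70, tertiary = 0.45)),
                       age_slope = 0.004,
                       sex_slope = 0.03,
                       dose_slope = 3e-5,
                       severity_coupling = list(
                         early = c(primary = 0, secondary = 0.20, tertiary = 0),
                         late = c(primary = -0.22, secondary = -0.22, tertiary = 0)),
                       subject_sigma_jitter = 0.08,
                       sspi_mean = 11.8,
                       sspi_slope = 5,
                       sspi_noise = 3,
                       age_mean = 34,
                       age_sd = 9,
                       age_range = c(18, 65),
                       prop_male = 0.7,
                       dose_meanlog = 6.18,
                       dose_sdlog = 0.85,
                       duration_cutoff = 5) {
  if (target_primary <= 0 || target_primary > 1) {
    abort_parameter("`target_primary` must be in (0, 1]")
  }
  need <- c("primary", "secondary", "tertiary")
  if (!all(need %in% names(mu)) || !all(need %in% names(sigma))) {
    abort_parameter("`mu` and `sigma` need primary/secondary/tertiary entries")
  }
  if (any(abs(mu) >= 1)) abort_parameter("class means must lie in (-1, 1)")
  if (!(mu[["primary"]] > mu[["secondary"]] &&
        mu[["secondary"]] > mu[["tertiary"]])) {
    abort_parameter("class means must decrease with path order")
  }
  if (any(sigma <= 0)) abort_parameter("class spreads must be > 0")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d regions, T = %d, n = %d control / %d early / %d late\n",
              x$n_regions, x$n_timepoints, x$n_control, x$n_early, x$n_late))
  invisible(x)
}

#' Generate a synthetic structural network
#'
#' Nodes are placed uniformly in the unit cube and edges realized with
#' probability decaying exponentially in Euclidean distance.  The decay
#' scale is calibrated by bisection so the expected edge density (the
#' primary-pair proportion) hits the target; distance decay then yields the
#' secondary/tertiary split of the remaining pairs.  The graph is made
#' connected by bridging nearest components, and streamline counts on
#' present edges are negative-binomial, floored at one.
#'
#' @param n_regions node count.
#' @param target_primary target proportion of directly connected pairs;
#'   1 gives the complete graph.
#' @param decay_shape distance-decay exponent (see [sim_config()]).
#' @param count_mean,count_dispersion negative-binomial parameters.
#' @param seed optional RNG seed.
#' @param template optional anatomical template from
#'   [structural_template()]; subjects of one cohort share a template so
#'   their networks are correlated realizations of the same anatomy, the
#'   way real subjects share an atlas.  When `NULL` a fresh template is
#'   drawn.
#' @return list: `counts` (streamline matrix), `adjacency`,
#'   `path_classes` (truth `path_class_matrix`), `coords`.
#' @export
generate_structural_network <- function(n_regions = 90L,
                                        target_primary = 0.278,
                                        decay_shape = 2.5,
                                        count_mean = 25,
                                        count_dispersion = 0.8,
                                        seed = NULL,
                                        template = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(template)) {
    template <- structural_template(n_regions, target_primary, decay_shape)
  }
  n <- template$n
  if (is.null(template$edge_prob)) {          # complete graph
    adj <- matrix(1L, n, n); diag(adj) <- 0L
  } else {
    e <- rbinom(length(template$edge_prob), 1L, template$edge_prob)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- e
    adj <- adj + t(adj)
    adj <- bridge_components(adj, template$dist)
  }

  ne <- sum(adj[upper.tri(adj)])
  counts <- matrix(0L, n, n)
  cnt <- pmax(1L, rnbinom(ne, mu = count_mean, size = count_dispersion))
  counts[upper.tri(counts)][adj[upper.tri(adj)] == 1L] <- cnt
  counts <- counts + t(counts)
  storage.mode(counts) <- "integer"

  list(counts = counts, adjacency = structure(adj, min_streamlines = 1L),
       path_classes = classify_paths(adj), coords = template$coords)
}

#' Anatomical template for a synthetic cohort
#'
#' Places regions uniformly in the unit cube and assigns every unordered
#' pair an edge probability decaying with Euclidean distance,
#' `p = exp(-(d / s)^shape)`, with the scale `s` calibrated by bisection so
#' the expected edge density equals the primary-pair target.  Subject
#' networks drawn from one template agree on most pair classes, emulating
#' the shared anatomy of a real cohort.
#'
#' @inheritParams generate_structural_network
#' @return list: `n`, `coords`, `dist`, `edge_prob` (upper-triangle vector;
#'   `NULL` for the complete graph).
#' @export
structural_template <- function(n_regions = 90L, target_primary = 0.278,
                                decay_shape = 2.5) {
  if (target_primary <= 0 || target_primary > 1) {
    abort_parameter("`target_primary` must be in (0, 1]")
  }
  n <- as.integer(n_regions)
  coords <- matrix(runif(3 * n), n, 3)
  D <- as.matrix(dist(coords))
  if (target_primary >= 0.999) {
    return(list(n = n, coords = coords, dist = D, edge_prob = NULL))
  }
  dv <- D[upper.tri(D)]
  # bisection on the decay scale: expected density mean(exp(-(d/s)^shape))
  # is monotone increasing in s
  dpow <- dv^decay_shape
  f <- function(s) mean(exp(-dpow / s^decay_shape))
  lo <- 1e-4; hi <- 100
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_primary) lo <- mid else hi <- mid
  }
  list(n = n, coords = coords, dist = D,
       edge_prob = exp(-dpow / ((lo + hi) / 2)^decay_shape))
}

# Join graph components by adding the shortest available bridge edge.
bridge_components <- function(adj, D) {
  repeat {
    g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no == 1) return(adj)
    a <- which(comp$membership == 1)
    b <- which(comp$membership != 1)
    Dab <- D[a, b, drop = FALSE]
    k <- which(Dab == min(Dab), arr.ind = TRUE)[1, ]
    i <- a[k[1]]; j <- b[k[2]]
    adj[i, j] <- adj[j, i] <- 1L
  }
}

#' Build a target correlation matrix from path classes
#'
#' Off-diagonal target correlations are drawn per pair from a normal with
#' the class mean and spread, truncated to (-0.99, 0.99), then the matrix
#' is projected to the nearest symmetric positive-definite correlation
#' matrix by eigenvalue clipping (floor 1e-6) and re-normalization to a
#' unit diagonal.  The mean absolute off-diagonal change introduced by the
#' projection is attached as attribute `distortion`.
#'
#' @param pcm `path_class_matrix`.
#' @param mu,sigma named class means and spreads; entries for `higher` and
#'   `disconnected` default to weak connectivity (0.03 / 0) at the tertiary
#'   spread when absent.
#' @param seed optional RNG seed.
#' @return positive-definite correlation matrix.
#' @export
build_target_covariance <- function(pcm, mu, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- c(mu, higher = unname(mu["tertiary"]) * 0.5, disconnected = 0)[
    !duplicated(c(names(mu), "higher", "disconnected"))]
  mu <- mu[c("primary", "secondary", "tertiary", "higher", "disconnected")]
  sig <- c(sigma, higher = unname(sigma["tertiary"]),
           disconnected = unname(sigma["tertiary"]))[
    !duplicated(c(names(sigma), "higher", "disconnected"))]
  sig <- sig[c("primary", "secondary", "tertiary", "higher", "disconnected")]
  if (!(mu[["primary"]] > mu[["secondary"]] &&
        mu[["secondary"]] > mu[["tertiary"]])) {
    abort_parameter("class means must decrease with path order")
  }

  n <- nrow(pcm)
  lab <- path_class_label(upper_pairs(unclass(pcm)))
  r <- rnorm(length(lab), mu[lab], sig[lab])
  for (i in 1:100) {
    out <- abs(r) >= 0.99
    if (!any(out)) break
    r[out] <- rnorm(sum(out), mu[lab[out]], sig[lab[out]])
  }
  r[abs(r) >= 0.99] <- sign(r[abs(r) >= 0.99]) * 0.98
  C <- matrix(0, n, n)
  C[upper.tri(C)] <- r
  C <- C + t(C)
  diag(C) <- 1

  proj <- nearest_spd_correlation(C)
  attr(proj, "distortion") <- mean(abs(proj[upper.tri(proj)] - r))
  attr(proj, "target_values") <- r  # pre-projection draws, upper triangle
  proj
}

# Eigenvalue clipping at 1e-6, then renormalization to unit diagonal.
nearest_spd_correlation <- function(C, floor = 1e-6, max_iter = 5) {
  for (i in seq_len(max_iter)) {
    e <- eigen(C, symmetric = TRUE)
    if (min(e$values) >= floor) break
    vals <- pmax(e$values, floor)
    C <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
    C <- (C + t(C)) / 2
    diag(C) <- 1
  }
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort_validation("positive-definite projection failed")
  }
  C
}

#' Sample Gaussian time series with a given covariance
#'
#' `T` independent zero-mean Gaussian draws with the supplied covariance
#' (a stand-in for preprocessed BOLD: the pipeline only consumes
#' correlations, so any covariance-faithful generator suffices).
#'
#' @param cov positive-definite covariance matrix.
#' @param n_timepoints number of rows to draw.
#' @param seed optional RNG seed.
#' @return T x N numeric matrix.
#' @export
sample_timeseries <- function(cov, n_timepoints, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_square(cov, "covariance")
  if (max(abs(cov - t(cov))) > 1e-8) abort_validation("covariance must be symmetric")
  R <- tryCatch(chol(cov),
                error = function(e) abort_validation("covariance is not positive definite"))
  if (n_timepoints < nrow(cov)) {
    warn(sprintf("T = %d < N = %d regions; correlation estimates will be rank-deficient",
                 n_timepoints, nrow(cov)))
  }
  matrix(rnorm(n_timepoints * nrow(cov)), n_timepoints) %*% R
}

#' Simulate a complete cohort
#'
#' Draws subject metadata (age, sex, dose, duration, latent severity and
#' symptom score), a structural network per subject, class-dependent target
#' correlations whose spread carries the designed group, covariate and
#' severity effects, and Gaussian time series.  Ground truth (per-subject
#' effective spreads, severity, true path classes) is attached.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; the same config and seed reproduce the cohort
#'   exactly.
#' @return an `fce_cohort` with a `truth` element (list: `sigma` tibble of
#'   per-subject effective class spreads, `path_classes` list,
#'   `config`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  n_pat <- cf$n_early + cf$n_late
  n_all <- n_pat + cf$n_control
  ids <- sprintf("S%03d", seq_len(n_all))
  group <- c(rep("patient", n_pat), rep("control", cf$n_control))
  stage <- c(rep("early", cf$n_early), rep("late", cf$n_late),
             rep("control", cf$n_control))

  age <- pmin(pmax(rnorm(n_all, cf$age_mean, cf$age_sd), cf$age_range[1]),
              cf$age_range[2])
  sex <- ifelse(runif(n_all) < cf$prop_male, "M", "F")
  dose <- ifelse(group == "patient",
                 rlnorm(n_all, cf$dose_meanlog, cf$dose_sdlog), 0)
  duration <- rep(NA_real_, n_all)
  duration[stage == "early"] <- runif(cf$n_early, 0.5,
                                      cf$duration_cutoff - 0.1)
  duration[stage == "late"] <- cf$duration_cutoff +
    pmin(rexp(cf$n_late, 1 / 6), 23)
  severity <- ifelse(group == "patient", rnorm(n_all), 0)
  sspi <- ifelse(group == "patient",
                 pmax(cf$sspi_mean + cf$sspi_slope * severity +
                        rnorm(n_all, 0, cf$sspi_noise), 0), NA_real_)

  cohort <- tibble::tibble(subject_id = ids, group = group, age = age,
                           sex = sex, dose = dose, duration = duration,
                           symptom_score = sspi)

  # one anatomical template per cohort; subjects are correlated realizations
  template <- structural_template(cf$n_regions, cf$target_primary,
                                  cf$decay_shape)

  classes <- c("primary", "secondary", "tertiary")
  streamlines <- timeseries <- pcms <- setNames(vector("list", n_all), ids)
  sigma_rows <- vector("list", n_all)
  for (k in seq_len(n_all)) {
    net <- generate_structural_network(cf$n_regions, cf$target_primary,
                                       cf$decay_shape, cf$count_mean,
                                       cf$count_dispersion,
                                       template = template)
    streamlines[[k]] <- net$counts
    pcms[[k]] <- net$path_classes

    gmult <- cf$group_sigma_mult[[stage[k]]][classes]
    coup <- if (stage[k] == "control") setNames(numeric(3), classes)
            else cf$severity_coupling[[stage[k]]][classes]
    jitter <- rnorm(1, 0, cf$subject_sigma_jitter)
    log_sigma <- log(cf$sigma[classes]) + log(gmult) +
      cf$age_slope * (age[k] - cf$age_mean) +
      cf$sex_slope * sex_code(sex[k]) +
      cf$dose_slope * dose[k] +
      coup * severity[k] + jitter
    sig_k <- exp(log_sigma)

    cov <- build_target_covariance(net$path_classes, cf$mu[classes], sig_k)
    timeseries[[k]] <- sample_timeseries(cov, cf$n_timepoints)
    sigma_rows[[k]] <- tibble::tibble(subject_id = ids[k], class = classes,
                                      sigma_effective = unname(sig_k),
                                      severity = severity[k],
                                      stage = stage[k])
  }

  new_fce_cohort(cohort, streamlines, timeseries,
                 truth = list(sigma = dplyr::bind_rows(sigma_rows),
                              path_classes = pcms, config = cf,
                              seed = seed))
}

#' Write a cohort (with ground truth) to a directory
#'
#' Layout: `cohort.csv`, `streamlines_<id>.tsv`, `timeseries_<id>.tsv`, a
#' `truth/` subdirectory with effective spreads and true path-class
#' matrices, and an effective simulation-config copy.
#'
#' @param cohort_data an `fce_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_data, dir) {
  stopifnot(inherits(cohort_data, "fce_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_table(cohort_data$cohort, file.path(dir, "cohort.csv"))
  for (id in cohort_data$cohort$subject_id) {
    write_matrix(cohort_data$streamlines[[id]],
                 file.path(dir, sprintf("streamlines_%s.tsv", id)))
    write_matrix(cohort_data$timeseries[[id]],
                 file.path(dir, sprintf("timeseries_%s.tsv", id)))
  }
  if (!is.null(cohort_data$truth)) {
    td <- file.path(dir, "truth")
    dir.create(td, showWarnings = FALSE)
    write.table(cohort_data$truth$sigma, file.path(td, "sigma_effective.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    for (id in names(cohort_data$truth$path_classes)) {
      write_path_class_matrix(cohort_data$truth$path_classes[[id]],
                              file.path(td, sprintf("pathclass_%s.tsv", id)))
    }
    cfg <- cohort_data$truth$config
    flat <- lapply(unclass(cfg), function(v) if (is.list(v)) lapply(v, as.list) else v)
    yaml::write_yaml(flat, file.path(dir, "sim_config.yml"))
  }
  invisible(dir)
}
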