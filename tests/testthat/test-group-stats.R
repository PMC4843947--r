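test_that("residualization removes linear covariate effects exactly", {
  age <- c(20, 25, 30, 40, 55, 60)
  y <- 3 * age + 7
  r <- residualize(y, data.frame(age = age))
  expect_equal(r, rep(mean(y), 6))

  # an all-zero covariate (dose in controls) changes nothing
  set.seed(161)
  y2 <- rnorm(20)
  covs <- data.frame(age = rnorm(20, 35, 8), dose = 0)
  expect_equal(residualize(y2, covs),
               residualize(y2, covs["age"]))

  expect_error(residualize(y2, data.frame(a = covs$age, b = 2 * covs$age)),
               "collinear")
})

test_that("residuals are orthogonal to every covariate column", {
  set.seed(171)
  for (i in 1:10) {
    n <- sample(30:70, 1)
    covs <- data.frame(age = rnorm(n, 35, 9),
                       sex = rbinom(n, 1, 0.5),
                       dose = ifelse(rbinom(n, 1, 0.5) == 1,
                                     rlnorm(n, 6, 0.8), 0))
    y <- rnorm(n) + 0.02 * covs$age - 0.3 * covs$sex
    r <- residualize(y, covs) - mean(y)
    for (j in seq_len(ncol(covs))) {
      cc <- scale(covs[[j]], scale = FALSE)
      expect_lt(abs(sum(r * cc)), 1e-8)
    }
    expect_equal(mean(residualize(y, covs)), mean(y))
  }
})

test_that("two-sample comparison matches the textbook pooled-t oracle", {
  out <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$mean_patient - out$mean_control, 1)
  expect_equal(out$cohen_d, 1)
  expect_equal(out$direction, 1)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$cohen_d, 0)
  expect_equal(same$p_value, 1)

  set.seed(181)
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20, 0.4)
    got <- compare_groups(x, y)
    want <- oracle_pooled_t(x, y)
    expect_equal(got$t_stat, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_equal(got$cohen_d, want$d, tolerance = 1e-10)
    # group swap: d invariant, t flips sign
    sw <- compare_groups(y, x)
    expect_equal(sw$cohen_d, got$cohen_d)
    expect_equal(sw$t_stat, -got$t_stat)
  }

  expect_error(compare_groups(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("symptom correlation reproduces the closed-form p of Pearson r", {
  fce <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_with_symptoms(fce, 2 * fce + 1)$r, 1)
  expect_equal(correlate_with_symptoms(fce, -3 * fce)$r, -1)

  set.seed(191)
  x <- rnorm(9); y <- rnorm(9, 0.2 * x)
  got <- correlate_with_symptoms(x, y)
  expect_equal(got$p_value, oracle_cor_p(x, y), tolerance = 1e-12)
  expect_error(correlate_with_symptoms(rep(1, 5), rnorm(5)), "constant")
  expect_error(correlate_with_symptoms(1:2, 1:2), "at least 3")
})

test_that("duration strata split patients at the cutoff", {
  co <- simple_cohort_table(letters[1:4],
                            c("patient", "patient", "patient", "control"),
                            duration = c(1, 5, 10, NA))
  st <- add_duration_stratum(co, cutoff = 5)
  expect_equal(st$duration_stratum, c("early", "late", "late", NA))
})

test_that("relabeled controls yield zero effect sizes in the full report", {
  # patients are byte-identical copies of controls: every d must be ~0
  ids_c <- sprintf("c%02d", 1:10)
  ids_p <- sprintf("p%02d", 1:10)
  set.seed(201)
  ent <- rnorm(10, 4, 0.3)
  fce_tab <- tibble::tibble(
    subject_id = rep(c(ids_c, ids_p), each = 2),
    stratum = rep(c("whole_brain", "secondary"), 20),
    entropy_bits = rep(rep(ent, each = 2), 2),
    n_links = 100L, undefined = FALSE, n_bins = 100L,
    bin_lo = -1, bin_hi = 1, transform = "raw_r", estimator = "plugin")
  cohort <- tibble::tibble(
    subject_id = c(ids_c, ids_p),
    group = rep(c("control", "patient"), each = 10),
    age = rep(seq(25, 43, 2), 2), sex = rep(rep(c("M", "F"), 5), 2),
    dose = 0, duration = c(rep(NA, 10), rep(2, 10)),
    symptom_score = c(rep(NA, 10), rnorm(10, 12, 4)))
  rep <- run_full_comparison(fce_tab, cohort)
  done <- dplyr::filter(tidy(rep), !flagged)
  expect_true(all(abs(done$cohen_d) < 1e-10))
  expect_true(all(done$p_value > 0.999))
})

test_that("a duration stratum with too few patients is flagged, not fatal", {
  ids <- c(sprintf("c%d", 1:6), "p1", "p2", "p3")
  set.seed(211)
  fce_tab <- tibble::tibble(
    subject_id = ids, stratum = "whole_brain",
    entropy_bits = rnorm(9, 4, 0.2), n_links = 50L, undefined = FALSE,
    n_bins = 100L, bin_lo = -1, bin_hi = 1, transform = "raw_r",
    estimator = "plugin")
  cohort <- tibble::tibble(
    subject_id = ids, group = c(rep("control", 6), rep("patient", 3)),
    age = seq(25, 45, length.out = 9), sex = rep(c("M", "F", "M"), 3),
    dose = c(rep(0, 6), 200, 300, 400),
    duration = c(rep(NA, 6), 2, 2, 12),   # only one late patient
    symptom_score = c(rep(NA, 6), 10, 15, 20))
  rep <- run_full_comparison(fce_tab, cohort)
  tt <- tidy(rep)
  expect_true(all(tt$flagged[tt$duration_stratum == "late"]))
  expect_false(any(tt$flagged[tt$duration_stratum == "early"]))
  expect_equal(glance(rep)$n_tests, sum(!tt$flagged))
})

test_that("threshold sweep is a no-op when all counts clear every threshold", {
  set.seed(221)
  n <- 12
  adj <- random_adjacency(n, 0.4)
  sl <- counts_from_adjacency(adj, 5L)  # every edge count >= 3
  ids <- letters[1:8]
  grp <- rep(c("patient", "control"), each = 4)
  cohort <- simple_cohort_table(ids, grp,
                                duration = c(2, 3, 2, 4, NA, NA, NA, NA),
                                symptom = c(10, 14, 8, 20, NA, NA, NA, NA))
  ts <- lapply(ids, function(i) matrix(rnorm(n * 40), 40, n))
  cd <- manual_cohort(setNames(rep(list(sl), 8), ids), setNames(ts, ids), cohort)
  sw <- threshold_sensitivity(cd, fce_config(n_bins = 16), thresholds = 1:3)
  expect_true(all(sw$agreement$mean_agreement == 1))
  expect_true(all(sw$agreement$min_agreement == 1))

  # counts of exactly 1 on some edges: classes change monotonically
  sl2 <- sl
  edge <- which(upper.tri(sl2) & sl2 > 0)[1:3]
  sl2[edge] <- 1L
  sl2[lower.tri(sl2)] <- t(sl2)[lower.tri(sl2)]
  storage.mode(sl2) <- "integer"
  r1 <- fcentropy:::path_class_rank(fcentropy:::upper_pairs(
    unclass(classify_paths(binarize_streamlines(sl2, 1)))))
  r2 <- fcentropy:::path_class_rank(fcentropy:::upper_pairs(
    unclass(classify_paths(binarize_streamlines(sl2, 2)))))
  expect_true(all(r2 >= r1))
  expect_true(any(r2 > r1))

  # cross-threshold agreement equals a brute-force tally
  cd2 <- manual_cohort(setNames(rep(list(sl2), 8), ids), setNames(ts, ids), cohort)
  sw2 <- threshold_sensitivity(cd2, fce_config(n_bins = 16), thresholds = 1:2)
  p1 <- classify_paths(binarize_streamlines(sl2, 1))
  p2 <- classify_paths(binarize_streamlines(sl2, 2))
  manual <- mean(fcentropy:::upper_pairs(unclass(p1)) ==
                 fcentropy:::upper_pairs(unclass(p2)))
  expect_equal(sw2$agreement$mean_agreement, manual)
})
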