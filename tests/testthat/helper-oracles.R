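# Independent oracles and small fixture builders used across the suite.

# Shortest-path classification by boolean matrix powers: the class of a pair
# is the smallest k with (A^k)[i, j] > 0, k up to n.  Independent of the
# breadth-first implementation in the package.
oracle_classify_matrix_power <- function(adj) {
  n <- nrow(adj)
  A <- (adj != 0) * 1
  reach <- A
  power <- A
  dist <- matrix(Inf, n, n)
  dist[A > 0] <- 1
  for (k in 2:n) {
    power <- (power %*% A > 0) * 1
    newly <- power > 0 & !is.finite(dist)
    dist[newly] <- k
  }
  cls <- matrix(0L, n, n)  # disconnected
  cls[dist == 1] <- 1L
  cls[dist == 2] <- 2L
  cls[dist == 3] <- 3L
  cls[is.finite(dist) & dist >= 4] <- 4L
  diag(cls) <- NA_integer_
  cls
}

# Random symmetric binary adjacency with edge density p.
random_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1L, p)
  a + t(a)
}

# Adjacency of a simple chain 1-2-...-n.
chain_adjacency <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

# Streamline matrix from an adjacency and a constant count.
counts_from_adjacency <- function(adj, count = 5L) {
  m <- adj * count
  storage.mode(m) <- "integer"
  m
}

# Hand-rolled two-sample pooled-t oracle (textbook formulas).
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * pt(-abs(t), df = nx + ny - 2)
  list(t = t, p = p, d = abs(mean(y) - mean(x)) / sqrt(sp2))
}

# Correlation p-value oracle via the t transform of r.
oracle_cor_p <- function(x, y) {
  r <- cor(x, y)
  t <- r * sqrt((length(x) - 2) / (1 - r^2))
  2 * pt(-abs(t), df = length(x) - 2)
}

# A tiny in-memory cohort around explicit streamline/timeseries matrices.
manual_cohort <- function(streamlines, timeseries, cohort) {
  fcentropy:::new_fce_cohort(cohort, streamlines, timeseries)
}

# Cohort table for n subjects with simple covariates.
simple_cohort_table <- function(ids, group, duration = NA_real_,
                                symptom = NA_real_) {
  tibble::tibble(subject_id = ids, group = group,
                 age = seq(25, 45, length.out = length(ids)),
                 sex = rep(c("M", "F"), length.out = length(ids)),
                 dose = ifelse(group == "patient", 300, 0),
                 duration = duration, symptom_score = symptom)
}
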