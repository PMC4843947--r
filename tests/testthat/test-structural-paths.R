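test_that("binarization applies the threshold and is monotone", {
  counts <- matrix(c(0L, 2L, 2L, 0L), 2)
  expect_equal(unclass(binarize_streamlines(counts, 1))[1, 2], 1L)
  expect_equal(unclass(binarize_streamlines(counts, 3))[1, 2], 0L)
  expect_true(all(binarize_streamlines(matrix(0L, 5, 5), 2) == 0))
  expect_error(binarize_streamlines(counts, 0), "integer >= 1")

  # raising the threshold never adds an edge
  set.seed(21)
  for (i in 1:10) {
    cm <- counts_from_adjacency(random_adjacency(15, 0.3), 1L) *
      matrix(sample(1:4, 225, replace = TRUE), 15)
    cm <- cm * upper.tri(cm); cm <- cm + t(cm)
    storage.mode(cm) <- "integer"
    prev <- binarize_streamlines(cm, 1)
    for (k in 2:4) {
      cur <- binarize_streamlines(cm, k)
      expect_true(all(cur <= prev))
      prev <- cur
    }
  }
})

test_that("path classification follows shortest path length", {
  # chain K-A-B-L: adjacent pairs primary, skip-one secondary, ends tertiary
  pcm <- classify_paths(chain_adjacency(4))
  lab <- fcentropy:::path_class_label(unclass(pcm))
  expect_equal(lab[1, 2], "primary")
  expect_equal(lab[2, 3], "primary")
  expect_equal(lab[3, 4], "primary")
  expect_equal(lab[1, 3], "secondary")
  expect_equal(lab[2, 4], "secondary")
  expect_equal(lab[1, 4], "tertiary")

  # star: leaves are secondary through the hub
  star <- matrix(0L, 3, 3); star[1, 2] <- star[2, 1] <- 1L
  star[2, 3] <- star[3, 2] <- 1L
  slab <- fcentropy:::path_class_label(unclass(classify_paths(star)))
  expect_equal(slab[1, 2], "primary")
  expect_equal(slab[2, 3], "primary")
  expect_equal(slab[1, 3], "secondary")

  # complete graph: every pair primary
  full <- matrix(1L, 10, 10); diag(full) <- 0L
  expect_true(all(unclass(classify_paths(full))[upper.tri(full)] == 1L))

  # isolated nodes are disconnected, not an error
  iso <- matrix(0L, 2, 2)
  expect_equal(unclass(classify_paths(iso))[1, 2],
               fcentropy:::PATH_CLASS_CODES[["disconnected"]])

  # a 5-chain has a pair at length 4: the "higher" label
  lab5 <- fcentropy:::path_class_label(unclass(classify_paths(chain_adjacency(5))))
  expect_equal(lab5[1, 5], "higher")
})

test_that("classification agrees with the boolean matrix-power oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    adj <- random_adjacency(n, runif(1, 0.02, 0.9))
    expect_equal(unclass(classify_paths(adj)),
                 oracle_classify_matrix_power(adj))
  }
})

test_that("class proportions tally every unordered pair exactly once", {
  pr <- path_class_proportions(classify_paths(chain_adjacency(4)))
  expect_equal(pr$proportion[pr$class == "primary"], 3 / 6)
  expect_equal(pr$proportion[pr$class == "secondary"], 2 / 6)
  expect_equal(pr$proportion[pr$class == "tertiary"], 1 / 6)

  full <- matrix(1L, 8, 8); diag(full) <- 0L
  prf <- path_class_proportions(classify_paths(full))
  expect_equal(prf$proportion[prf$class == "primary"], 1)

  pre <- path_class_proportions(classify_paths(matrix(0L, 6, 6)))
  expect_equal(pre$proportion[pre$class == "disconnected"], 1)

  # merge policy folds higher-order pairs into tertiary
  pcm5 <- classify_paths(chain_adjacency(5))
  sep <- path_class_proportions(pcm5, "separate")
  mrg <- path_class_proportions(pcm5, "merge_into_tertiary")
  expect_equal(mrg$n_pairs[mrg$class == "tertiary"],
               sum(sep$n_pairs[sep$class %in% c("tertiary", "higher")]))

  # tally conservation across random graphs and thresholds
  set.seed(41)
  for (i in 1:10) {
    n <- sample(6:25, 1)
    pr <- path_class_proportions(classify_paths(random_adjacency(n, runif(1))))
    expect_equal(sum(pr$n_pairs), n * (n - 1) / 2)
    expect_equal(sum(pr$proportion), 1)
  }
})

test_that("raising the threshold never lowers a pair's path order", {
  set.seed(51)
  for (i in 1:10) {
    n <- 20
    cm <- random_adjacency(n, 0.25)
    cnt <- matrix(sample(1:4, n * n, replace = TRUE), n)
    cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
    cm <- cm * cnt
    storage.mode(cm) <- "integer"
    ranks <- lapply(1:4, function(k) {
      fcentropy:::path_class_rank(
        fcentropy:::upper_pairs(unclass(classify_paths(binarize_streamlines(cm, k)))))
    })
    for (k in 2:4) expect_true(all(ranks[[k]] >= ranks[[k - 1]]))
  }
})

test_that("consensus takes the per-pair mode with ties toward lower order", {
  p1 <- classify_paths(chain_adjacency(4))
  expect_equal(unclass(consensus_path_class(list(p1, p1, p1))), unclass(p1))

  # majority: primary in 2 of 3 wins
  full <- classify_paths({a <- matrix(1L, 4, 4); diag(a) <- 0L; a})
  cons <- consensus_path_class(list(full, full, p1))
  expect_true(all(fcentropy:::upper_pairs(unclass(cons)) == 1L))

  # tie between primary and secondary resolves to primary
  cons2 <- consensus_path_class(list(full, p1))
  expect_equal(unclass(cons2)[1, 3], 1L)
  expect_equal(unclass(cons2)[1, 4], 1L)

  expect_error(consensus_path_class(list()), "at least one")
})

test_that("classification agreement matches a brute-force pair tally", {
  a <- classify_paths({m <- matrix(1L, 3, 3); diag(m) <- 0L; m})
  expect_equal(class_agreement(a, a)$fraction, 1)
  expect_true(all(class_agreement(a, a)$per_class$frac_union[1] == 1))

  b <- classify_paths(chain_adjacency(3))  # pair (1,3) secondary
  ab <- class_agreement(a, b)
  expect_equal(ab$n_agree, 2L)

  set.seed(61)
  x <- classify_paths(random_adjacency(10, 0.3))
  y <- classify_paths(random_adjacency(10, 0.3))
  res <- class_agreement(x, y)
  # brute force over all 45 unordered pairs
  cx <- unclass(x); cy <- unclass(y)
  agree <- 0; per <- setNames(numeric(5), fcentropy:::PATH_CLASS_ORDER)
  union_n <- per
  for (i in 1:9) for (j in (i + 1):10) {
    if (cx[i, j] == cy[i, j]) agree <- agree + 1
    for (cl in names(per)) {
      code <- fcentropy:::PATH_CLASS_CODES[[cl]]
      if (cx[i, j] == code && cy[i, j] == code) per[cl] <- per[cl] + 1
      if (cx[i, j] == code || cy[i, j] == code) union_n[cl] <- union_n[cl] + 1
    }
  }
  expect_equal(res$n_agree, agree)
  expect_equal(res$per_class$n_both, unname(per[res$per_class$class]))
  expect_equal(res$per_class$n_union, unname(union_n[res$per_class$class]))
  expect_error(class_agreement(x, classify_paths(random_adjacency(8, .3))),
               "differ in size")
})

test_that("path-class matrices round-trip through integer-coded text", {
  set.seed(71)
  pcm <- classify_paths(random_adjacency(15, 0.2))
  f <- withr::local_tempfile()
  write_path_class_matrix(pcm, f)
  back <- read_path_class_matrix(f)
  expect_equal(unclass(back), unclass(pcm))
})
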