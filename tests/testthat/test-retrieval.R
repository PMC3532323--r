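test_that("average precision matches hand-computed and oracle values", {
  ranking <- paste0("c", 1:5)
  expect_equal(average_precision(ranking, c("c1", "c3"), 5),
               (1 + 2 / 3) / 2)
  expect_equal(average_precision(ranking, ranking, 5), 1)
  expect_equal(average_precision(ranking, "zzz", 5), 0)
  expect_error(average_precision(ranking, character(0), 3), "non-empty")
  expect_error(average_precision(ranking, "c1", 9), "exceeds")
})

test_that("average precision agrees with brute force on every small ranking", {
  for (n in c(3, 5)) {
    items <- paste0("i", seq_len(n))
    rel <- items[seq(1, n, by = 2)]
    perms <- all_perms(items)
    for (k in seq_len(n)) {
      got <- vapply(perms, average_precision, numeric(1),
                    relevant = rel, k = k)
      want <- vapply(perms, oracle_ap, numeric(1), relevant = rel, k = k)
      expect_identical(got, want)
    }
  }
  items <- paste0("i", 1:8)
  rel <- c("i1", "i4", "i6")
  perms <- all_perms(items)
  for (k in c(4L, 8L)) {
    got <- vapply(perms, average_precision, numeric(1),
                  relevant = rel, k = k)
    want <- vapply(perms, oracle_ap, numeric(1), relevant = rel, k = k)
    expect_identical(got, want)
  }
})

test_that("similarity matrix is a correlation with flagged degenerate rows", {
  set.seed(2)
  m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("c", 1:4), NULL))
  s <- similarity_matrix(m)
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 4))
  m2 <- rbind(m, c5 = m[1, ], c6 = -m[1, ])
  s2 <- similarity_matrix(m2)
  expect_equal(s2["c1", "c5"], 1)
  expect_equal(s2["c1", "c6"], -1)
  m3 <- rbind(m, flat = rep(2, 5))
  s3 <- similarity_matrix(m3)
  expect_identical(attr(s3, "zero_variance"), "flat")
  expect_true(all(s3["flat", colnames(s3) != "flat"] == 0))
})

test_that("map curve is exact on clustered data and near baseline on random", {
  # two perfect clusters with opposite feature patterns: MAP 1 below the
  # cluster size
  set.seed(4)
  pattern <- c(5, -5, 5, -5)
  feats <- rbind(matrix(rnorm(5 * 4), 5, 4, byrow = TRUE) +
                   matrix(pattern, 5, 4, byrow = TRUE),
                 matrix(rnorm(5 * 4), 5, 4, byrow = TRUE) -
                   matrix(pattern, 5, 4, byrow = TRUE))
  rownames(feats) <- paste0("c", 1:10)
  ann <- annotation_set(data.frame(compound = rownames(feats),
                                   label = rep(c("a", "b"), each = 5)))
  cu <- map_curve(similarity_matrix(feats), ann, ks = c(2, 4))
  expect_equal(cu$map, c(1, 1))
  expect_identical(cu$n_queries, c(10L, 10L))

  # random representation: MAP within Monte-Carlo error of the exact
  # analytic baseline
  set.seed(5)
  reps <- replicate(20, {
    r <- matrix(rnorm(30 * 8), 30, 8,
                dimnames = list(paste0("c", 1:30), NULL))
    ann2 <- annotation_set(data.frame(compound = paste0("c", 1:30),
                                      label = rep(c("a", "b", "c"), 10)))
    mean(map_curve(similarity_matrix(r), ann2, ks = c(5, 10, 15))$map) -
      mean(random_baseline_map(ann2, paste0("c", 1:30), ks = c(5, 10, 15)))
  })
  expect_lt(abs(mean(reps)), 0.03)
})

test_that("analytic random baseline matches Monte-Carlo expectation", {
  set.seed(9)
  N <- 25; R <- 6
  for (k in c(3, 10, 24)) {
    mc <- mean(replicate(4000, {
      ranking <- sample(paste0("i", 1:N))
      oracle_ap(ranking, paste0("i", 1:R), k)
    }))
    expect_lt(abs(ccalink:::expected_ap_random(N, R, k) - mc), 0.015)
  }
})

test_that("map is invariant under rank-preserving similarity transforms", {
  set.seed(6)
  feats <- matrix(rnorm(20 * 6), 20, 6,
                  dimnames = list(paste0("c", 1:20), NULL))
  ann <- annotation_set(data.frame(compound = paste0("c", 1:20),
                                   label = rep(c("a", "b"), 10)))
  s <- similarity_matrix(feats)
  s2 <- tanh(2 * s)  # monotone transform preserves per-query ranking
  dimnames(s2) <- dimnames(s)
  expect_equal(map_curve(s, ann, ks = c(3, 6))$map,
               map_curve(s2, ann, ks = c(3, 6))$map)
})

test_that("sem shrinks with more queries", {
  set.seed(7)
  feats <- matrix(rnorm(60 * 6), 60, 6,
                  dimnames = list(sprintf("c%02d", 1:60), NULL))
  ann <- annotation_set(data.frame(compound = rownames(feats),
                                   label = rep(c("a", "b"), 30)))
  s <- similarity_matrix(feats)
  small <- map_curve(s, ann, ks = 10, queries = rownames(feats)[1:12])
  large <- map_curve(s, ann, ks = 10)
  expect_lt(large$sem, small$sem)
})

test_that("default depth grid covers 5 to 100 in 20 points", {
  expect_identical(formals(map_curve)$ks, quote(seq(5L, 100L, by = 5L)))
  set.seed(8)
  feats <- matrix(rnorm(120 * 5), 120, 5,
                  dimnames = list(sprintf("c%03d", 1:120), NULL))
  ann <- annotation_set(data.frame(compound = rownames(feats),
                                   label = rep(letters[1:4], 30)))
  cu <- map_curve(similarity_matrix(feats), ann)
  expect_identical(nrow(cu), 20L)
  expect_identical(cu$k, seq(5L, 100L, by = 5L))
})

test_that("compare_spaces returns aligned curves for all representations", {
  d <- simulate_joint_data(80, 8, 10, 2, c(0.9, 0.6), seed = 20)
  genes <- simulate_gene_responses(d$truth, 60, seed = 21)
  ann <- simulate_annotations(rownames(d$X), 4, d$truth, 0.9, seed = 22)
  fit <- fit_rcca(d$X, d$Y, 0.1, 0.01, 2, scale_x = FALSE)
  curves <- compare_spaces(d$X, d$Y, genes, fit, ann, ks = c(5, 10, 20),
                           components = 1:2)
  expect_setequal(names(curves), c("cca", "chem", "geneset", "gene"))
  for (cu in curves) expect_identical(cu$k, c(5L, 10L, 20L))
})
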