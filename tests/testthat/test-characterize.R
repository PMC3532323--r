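fit_small_study <- function(seed = 30, n = 60) {
  d <- simulate_joint_data(n, 6, 10, 2, c(0.9, 0.6), seed = seed)
  fit <- fit_rcca(d$X, d$Y, 0.1, 0.01, 2, scale_x = FALSE)
  list(d = d, fit = fit, split = split_subcomponents(fit))
}

test_that("top gene sets rank by association with the biological variate", {
  st <- fit_small_study()
  Y2 <- cbind(st$d$Y, mirror = st$fit$bio_variates[, 1])
  tg <- top_gene_sets(st$fit, Y2, 1, k = 5)
  expect_identical(tg$set[1], "mirror")
  expect_equal(tg$association[1], 1)
  expect_identical(nrow(top_gene_sets(st$fit, st$d$Y, 1, k = 10)), 10L)
  # constant column gets association zero
  Y3 <- cbind(st$d$Y, flat = 1)
  tg3 <- top_gene_sets(st$fit, Y3, 1, k = ncol(Y3))
  expect_equal(tg3$association[tg3$set == "flat"], 0)
})

test_that("top compounds rank by absolute score within the side", {
  st <- fit_small_study()
  tc <- top_compounds(st$split, 1, "A", k = 20)
  expect_lte(nrow(tc), 20)
  expect_true(all(tc$score > 0))
  expect_true(!is.unsorted(rev(abs(tc$score))))
  small <- top_compounds(st$split, 1, "B", k = 1000)
  expect_identical(nrow(small), length(st$split$members[[1]]$B))
  # invariant to positive rescaling
  st2 <- st
  st2$split$scores <- st$split$scores * 7
  expect_identical(top_compounds(st2$split, 1, "A", 10)$compound,
                   tc$compound[1:10])
})

test_that("moderated t reduces to Student t at prior zero and stays finite", {
  set.seed(31)
  for (r in 1:10) {
    x <- rnorm(sample(3:12, 1))
    rt <- regularized_t(x, background_var = runif(1, 0.5, 2), prior_df = 0)
    st <- t.test(x)
    expect_lt(abs(rt$t - unname(st$statistic)), 1e-10)
    expect_lt(abs(rt$p - st$p.value), 1e-10)
  }
  # zero sample variance with a positive prior: finite statistic
  rt0 <- regularized_t(rep(2, 5), background_var = 1, prior_df = 4)
  expect_true(is.finite(rt0$t))
  expect_error(regularized_t(3, 1), "at least 2")
  expect_error(regularized_t(c(1, 2), 1, prior_df = -1), ">= 0")
})

test_that("moderated t is calibrated under the hierarchical null", {
  set.seed(32)
  g <- 4000; n <- 10; d0 <- 10
  sig2 <- d0 / rchisq(g, d0)
  vals <- matrix(rnorm(g * n, sd = rep(sqrt(sig2), each = n)), n, g,
                 dimnames = list(NULL, sprintf("g%04d", 1:g)))
  p <- vapply(seq_len(g), function(j)
    regularized_t(vals[, j], background_var = 1, prior_df = d0)$p,
    numeric(1))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("hypergeometric enrichment equals the exhaustive oracle", {
  uni <- paste0("g", 1:12)
  terms <- gene_set_collection(list(t1 = uni[1:4], t2 = uni[3:8],
                                    t3 = uni[10:12]), uni)
  set.seed(33)
  for (r in 1:8) {
    gl <- sample(uni, sample(2:6, 1))
    enr <- term_enrichment(gl, terms)
    for (i in seq_len(nrow(enr))) {
      tm <- enr$term[i]
      ov <- length(intersect(terms$sets[[tm]], gl))
      expected <- if (ov == 0) 1 else
        oracle_hyper_tail(uni, terms$sets[[tm]], length(gl), ov)
      expect_equal(enr$p[i], expected, tolerance = 1e-12)
    }
  }
  # exact-list match on a small universe: closed-form tail
  enr2 <- term_enrichment(uni[1:4], terms)
  expect_equal(enr2$p[enr2$term == "t1"],
               1 / choose(12, 4), tolerance = 1e-12)
  expect_equal(enr2$p[enr2$term == "t3"], 1)
  expect_error(term_enrichment(c("nope"), terms), "outside")
})

test_that("tanimoto has the documented set-algebra behaviour", {
  expect_identical(tanimoto(c("a", "b"), c("a", "b")), 1)
  expect_identical(tanimoto(c("a"), c("b")), 0)
  expect_equal(tanimoto(c("a", "b"), c("b", "c")), 1 / 3)
  expect_identical(tanimoto(character(0), character(0)), 0)
  set.seed(34)
  for (r in 1:10) {
    a <- sample(letters, 5); b <- sample(letters, 7)
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
  }
})

test_that("target enrichment p-values behave at the extremes", {
  pool <- sprintf("c%03d", 1:200)
  ann <- annotation_set(data.frame(
    compound = c(pool, sprintf("c%03d", 1:20)),
    label = c(paste0("t", rep(1:100, 2)), rep("shared", 20))))
  hit <- target_enrichment(sprintf("c%03d", 1:20), ann, n_draws = 200,
                           seed = 1)
  expect_gte(hit$statistic, 1)
  # compounds with no annotations at all: statistic 0, p near 1
  none <- target_enrichment(c("zz1", "zz2", "zz3"), ann, n_draws = 200,
                            seed = 2)
  expect_identical(none$statistic, 0L)
  expect_gt(none$p, 0.5)
  expect_error(target_enrichment("c001", ann), "at least 2")

  # observed sharing unreachable by random draws -> minimal p: the 20 list
  # compounds share ten exclusive pairwise targets (statistic 10); a random
  # draw would have to reproduce the whole list to match it
  ann2 <- annotation_set(data.frame(
    compound = c(paste0("s", 1:20), pool),
    label = c(paste0("pair", rep(1:10, each = 2)),
              paste0("u", seq_along(pool)))))
  ex <- target_enrichment(paste0("s", 1:20), ann2, n_draws = 100, seed = 3)
  expect_identical(ex$statistic, 10L)
  expect_equal(ex$p, 1 / 101)
  expect_identical(formals(target_enrichment)$n_draws, 1000L)
})

test_that("target enrichment p is a valid Monte-Carlo p-value under the null", {
  set.seed(35)
  pool <- sprintf("c%03d", 1:60)
  ann <- annotation_set(data.frame(compound = pool,
                                   label = paste0("t", rep(1:20, 3))))
  ps <- replicate(100, {
    target_enrichment(sample(pool, 10), ann, n_draws = 39,
                      seed = sample.int(1e6, 1))$p
  })
  se <- sqrt(0.05 * 0.95 / 100)
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * se)
})

test_that("subcomponent de genes recover planted signal blocks", {
  dd <- simulate_shared_compound_data(seed = 40)
  fit <- fit_rcca(dd$X, dd$Y, 0.1, 0.01, 2, scale_x = FALSE)
  split <- split_subcomponents(fit)
  g1 <- component_de_genes(fit, split, dd$responses, dd$Y, dd$collection,
                           component = 1, side = "A")
  expect_true(all(g1$p < 0.05))
  expect_lte(length(attr(g1, "top")), 30)
  expect_gt(nrow(g1), 0)
})

test_that("subcomponent similarity contrasts gene overlap with compound overlap", {
  r1 <- structure(list(component = 1, side = "A",
                       top_compounds = data.frame(compound = paste0("c", 1:20)),
                       top_genes = paste0("g", 1:30)),
                  class = "subcomponent_report")
  r2 <- structure(list(component = 2, side = "A",
                       top_compounds = data.frame(compound = paste0("c", 11:30)),
                       top_genes = paste0("h", 1:30)),
                  class = "subcomponent_report")
  sim <- subcomponent_similarity(list(r1, r2))
  expect_identical(sim$biological["1A", "1A"], 1)
  expect_identical(sim$compound_overlap["1A", "1A"], 20L)
  expect_identical(sim$compound_overlap["1A", "2A"], 10L)
  expect_identical(sim$biological["1A", "2A"], 0)
  expect_equal(sim$biological, t(sim$biological))
  expect_equal(sim$compound_overlap, t(sim$compound_overlap))
})

test_that("eye diagram table has the documented shape and weights", {
  st <- fit_small_study()
  eye <- eye_diagram_table(st$fit, st$split, st$d$Y, st$d$X,
                           components = 1:2, k_sets = 5)
  per_comp <- subset(eye, component == 1)
  expect_identical(sum(per_comp$kind == "gene-set"), 5L)
  expect_identical(sum(per_comp$kind == "descriptor") %% ncol(st$d$X), 0L)
  # gene-set weights reproduce the top_gene_sets ranking
  tg <- top_gene_sets(st$fit, st$d$Y, 1, k = 5)
  expect_identical(per_comp$element[per_comp$kind == "gene-set"], tg$set)
  expect_equal(per_comp$weight[per_comp$kind == "gene-set"], tg$association)
})
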