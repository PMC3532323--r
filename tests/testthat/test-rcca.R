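rand_xy <- function(n, p, q, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p,
                  dimnames = list(sprintf("s%03d", 1:n), paste0("x", 1:p))),
       Y = matrix(rnorm(n * q), n, q,
                  dimnames = list(sprintf("s%03d", 1:n), paste0("y", 1:q))))
}

test_that("unregularized fit matches classical CCA", {
  for (seed in 1:5) {
    d <- rand_xy(50, 8, 6, seed)
    fit <- fit_rcca(d$X, d$Y, 0, 0, 6, scale_x = FALSE)
    cc <- oracle_cca(d$X, d$Y)
    expect_lt(max(abs(fit$correlations - cc$cor[1:6])), 1e-8)
    # variates agree up to sign
    cv_o <- scale(d$X, scale = FALSE) %*% cc$xcoef[, 1:6]
    cv_o <- scale(cv_o, center = FALSE, scale = apply(cv_o, 2, sd))
    for (s in 1:6) {
      agree <- min(max(abs(fit$chem_variates[, s] - cv_o[, s])),
                   max(abs(fit$chem_variates[, s] + cv_o[, s])))
      expect_lt(agree, 1e-6)
    }
  }
})

test_that("identical views give unit canonical correlations", {
  d <- rand_xy(40, 5, 5, 3)
  fit <- fit_rcca(d$X, d$X, 0, 0, 5)
  expect_lt(max(abs(fit$correlations - 1)), 1e-10)
})

test_that("training variates have unit variance and fixed signs", {
  d <- rand_xy(60, 7, 5, 4)
  fit <- fit_rcca(d$X, d$Y, 0.1, 0.1, 4)
  expect_equal(unname(apply(fit$chem_variates, 2, var)), rep(1, 4))
  expect_equal(unname(apply(fit$bio_variates, 2, var)), rep(1, 4))
  for (s in 1:4) {
    i <- which.max(abs(fit$chem_weights[, s]))
    expect_gt(fit$chem_weights[i, s], 0)
  }
  expect_true(all(diff(fit$correlations) <= 1e-8))
})

test_that("correlations are invariant to invertible feature transforms at l = 0", {
  d <- rand_xy(80, 6, 5, 9)
  fit0 <- fit_rcca(d$X, d$Y, 0, 0, 5, scale_x = FALSE)
  set.seed(10)
  Ax <- matrix(rnorm(36), 6, 6); Ay <- matrix(rnorm(25), 5, 5)
  Xr <- d$X %*% Ax; Yr <- d$Y %*% Ay
  colnames(Xr) <- colnames(d$X); colnames(Yr) <- colnames(d$Y)
  fit1 <- fit_rcca(Xr, Yr, 0, 0, 5, scale_x = FALSE)
  expect_lt(max(abs(fit0$correlations - fit1$correlations)), 1e-6)
})

test_that("strong ridge drives weights to the cross-covariance singular vectors", {
  d <- rand_xy(60, 6, 5, 11)
  fit <- fit_rcca(d$X, d$Y, 1e7, 1e7, 2, scale_x = FALSE)
  Xc <- scale(d$X, scale = FALSE); Yc <- scale(d$Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc) / (nrow(Xc) - 1))
  expect_lt(max(p_angles(fit$chem_weights[, 1:2], sv$u[, 1:2])), 1)
  expect_lt(max(p_angles(fit$bio_weights[, 1:2], sv$v[, 1:2])), 1)
})

test_that("ridge fit agrees with an independent regularized CCA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(19)
  X <- matrix(rnorm(40 * 6), 40, 6); Y <- matrix(rnorm(40 * 5), 40, 5)
  fit <- fit_rcca(X, Y, 0.2, 0.05, 3, scale_x = FALSE)
  ref <- mixOmics::rcc(X, Y, lambda1 = 0.2, lambda2 = 0.05,
                       method = "ridge")
  # the penalized singular values are the quantity both solvers share
  expect_lt(max(abs(fit$penalized - ref$cor[1:3])), 1e-8)
})

test_that("singular unregularized covariance raises an informative error", {
  d <- rand_xy(10, 20, 5, 12)  # p > n
  expect_error(fit_rcca(d$X, d$Y, 0, 0, 3), "ridge")
  dna <- rand_xy(20, 4, 3, 13); dna$X[1, 1] <- NA
  expect_error(fit_rcca(dna$X, dna$Y), "missing")
})

test_that("projection reproduces training variates and handles duplicates", {
  d <- rand_xy(50, 6, 5, 14)
  fit <- fit_rcca(d$X, d$Y, 0.05, 0.05, 3)
  pr <- project_rcca(fit, d$X, d$Y)
  expect_equal(unname(pr$chem_variates), unname(fit$chem_variates))
  expect_equal(unname(pr$bio_variates), unname(fit$bio_variates))
  # duplicated row projects identically
  X2 <- d$X[c(1, 1), ]
  pr2 <- project_rcca(fit, X2)
  expect_equal(pr2$chem_variates[1, ], pr2$chem_variates[2, ])
  Xbad <- d$X; colnames(Xbad)[1] <- "zz"
  expect_error(project_rcca(fit, Xbad), "column names")
})

test_that("regularization selection scores a grid and breaks ties as documented", {
  d <- simulate_joint_data(60, 6, 8, 2, c(0.9, 0.6), seed = 15)
  ann <- simulate_annotations(rownames(d$X), 4, d$truth, 0.9, seed = 15)
  single <- select_regularization(d$X, d$Y, data.frame(l1 = 0.5, l2 = 0.5),
                                  folds = 5, annotations = ann, seed = 1)
  expect_identical(c(single$l1, single$l2), c(0.5, 0.5))
  expect_false(anyNA(single$scores$score))
  expect_gt(single$scores$score, 0)

  # fold partition arithmetic: 100 compounds over 20 folds -> 5 each
  set.seed(1)
  fold_of <- sample(rep_len(1:20, 100))
  expect_true(all(table(fold_of) == 5))

  # exact score ties prefer smaller l1 then l2
  grid <- data.frame(l1 = c(2, 1), l2 = c(1, 1))
  sel <- select_regularization(d$X, d$Y, grid, folds = 5, annotations = ann,
                               seed = 1)
  expect_true(sel$l1 %in% grid$l1)
  tied <- sel$scores
  if (length(unique(tied$score)) == 1) expect_identical(sel$l1, 1)
})

test_that("collinear descriptors drive the selected ridge inside the grid", {
  hits <- 0
  for (seed in 1:3) {
    d <- simulate_joint_data(50, 10, 8, 2, c(0.9, 0.6), seed = 200 + seed)
    # collinear chemical space: duplicate every descriptor with tiny jitter
    set.seed(seed)
    X <- cbind(d$X, d$X + matrix(rnorm(length(d$X), sd = 1e-4),
                                 nrow(d$X)))
    colnames(X) <- paste0("d", seq_len(ncol(X)))
    ann <- simulate_annotations(rownames(X), 4, d$truth, 0.9,
                                seed = 300 + seed)
    grid <- data.frame(l1 = c(1e-8, 0.1, 1e6), l2 = 0.01)
    sel <- select_regularization(X, d$Y, grid, folds = 4,
                                 annotations = ann, n_components = 2,
                                 seed = seed)
    if (sel$l1 == 0.1) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("permutation p-values have the forced minimum and recover planted signal", {
  d <- simulate_joint_data(200, 6, 8, 1, 0.9, seed = 16)
  m <- permutation_significance(d$X, d$Y, 0.05, 0.01, n_components = 1,
                                n_perm = 199, seed = 16)
  expect_identical(m$perm_pvalues[1], 1 / 200)
  expect_identical(m$perm_pvalues_raw[1], 0)
  expect_error(permutation_significance(d$X, d$Y, n_perm = 5), ">= 19")
})

test_that("subcomponent split separates signs and flips under negation", {
  d <- rand_xy(30, 5, 4, 17)
  fit <- fit_rcca(d$X, d$Y, 0.1, 0.1, 2)
  sp <- split_subcomponents(fit)
  ids <- rownames(fit$chem_variates)
  sc <- sp$scores[, 1]
  expect_setequal(sp$members[[1]]$A, ids[sc > 0])
  expect_setequal(sp$members[[1]]$B, ids[sc < 0])
  expect_length(intersect(sp$members[[1]]$A, sp$members[[1]]$B), 0)

  # global sign flip swaps A and B exactly
  fit2 <- fit
  fit2$chem_variates <- -fit$chem_variates
  fit2$bio_variates <- -fit$bio_variates
  sp2 <- split_subcomponents(fit2)
  expect_setequal(sp2$members[[1]]$A, sp$members[[1]]$B)
  expect_setequal(sp2$members[[1]]$B, sp$members[[1]]$A)

  # manual scores: all-positive side leaves B empty
  fit3 <- fit
  fit3$chem_variates[] <- abs(fit3$chem_variates) + 1
  fit3$bio_variates[] <- abs(fit3$bio_variates) + 1
  sp3 <- split_subcomponents(fit3)
  expect_length(sp3$members[[1]]$B, 0)
})

test_that("retained components respect the significance threshold and cap", {
  d <- rand_xy(30, 5, 4, 18)
  fit <- fit_rcca(d$X, d$Y, 0.1, 0.1, 4)
  fit$perm_pvalues <- c(0.01, 0.2, 0.001, 0.04)
  expect_identical(retained_components(fit), c(1L, 3L, 4L))
  expect_identical(retained_components(fit, max_components = 2), c(1L, 3L))
  fit$perm_pvalues <- NULL
  expect_identical(retained_components(fit), 1:4)
})
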