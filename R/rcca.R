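## Regularized canonical correlation analysis: the statistical core.
##
## Two views X (n x p, chemical descriptors) and Y (n x q, gene-set
## activations) are linked by projection pairs (w_s, v_s) maximizing the
## ridge-penalized correlation
##   w' Cxy v / sqrt((w' Cxx w + l1 ||w||^2) (v' Cyy v + l2 ||v||^2)).
## The solution is the whitening decomposition: singular vectors of
##   M = (Cxx + l1 I)^{-1/2} Cxy (Cyy + l2 I)^{-1/2},
## equivalently eigenvectors of K = M M'. Successive components are
## uncorrelated in the regularized metric.

inv_sqrt_sym <- function(M, ridge, label) {
  e <- eigen(M + ridge * diag(nrow(M)), symmetric = TRUE)
  if (min(e$values) <= 1e-12)
    stop(sprintf(
      "regularized %s covariance is numerically singular (min eigenvalue %.2e); increase the ridge penalty", # nolint
      label, min(e$values)), call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Fit regularized canonical correlation analysis
#'
#' Centers (and optionally scales) both views, forms the feature-space
#' covariances `Cxx = X'X/(n-1)`, `Cyy`, `Cxy`, adds ridge penalties `l1`,
#' `l2` to the diagonals, and extracts paired projection vectors from the
#' singular value decomposition of the whitened cross-covariance. Reported
#' `correlations` are the sample correlations of each variate pair (the
#' quantity the model maximizes at `l = 0`); the penalized singular values
#' are kept in `penalized`. Weights are rescaled so every training variate
#' has unit sample variance, and signs are fixed so the largest-magnitude
#' entry of each chemical weight vector is positive.
#'
#' @param X Numeric matrix (compounds x descriptors), no missing values.
#' @param Y Numeric matrix (compounds x gene sets), same rows as `X`.
#' @param l1,l2 Non-negative ridge penalties for the two views.
#' @param n_components Number of components to retain (default
#'   `min(p, q)`).
#' @param scale_x,scale_y Standardize columns to unit variance before
#'   fitting (descriptor scales are typically heterogeneous, so `scale_x`
#'   defaults to `TRUE`; activations are already bounded, so `scale_y`
#'   defaults to `FALSE`).
#' @return An object of class `rcca_model`: `chem_weights` (p x S),
#'   `bio_weights` (q x S), `correlations`, `penalized`, `chem_variates`,
#'   `bio_variates` (n x S), `l1`, `l2`, centering/scaling vectors, and
#'   `perm_pvalues` (absent until [permutation_significance()] is run).
#' @examples
#' d <- simulate_joint_data(200, 8, 10, 2, c(0.8, 0.5), seed = 1)
#' fit <- fit_rcca(d$X, d$Y, l1 = 0.1, l2 = 0.01, n_components = 2)
#' fit$correlations
#' @export
fit_rcca <- function(X, Y, l1 = 0, l2 = 0, n_components = NULL,
                     scale_x = TRUE, scale_y = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_input("X and Y must have the same rows")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop_input("X and Y row ids are not aligned")
  if (anyNA(X) || anyNA(Y)) stop_input("inputs contain missing values")
  l1 <- check_number(l1, "l1", 0)
  l2 <- check_number(l2, "l2", 0)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n < 3) stop_input("need at least 3 samples")
  d <- if (is.null(n_components)) min(p, q) else
    check_count(n_components, "n_components")
  if (d > min(p, q))
    stop_input("n_components (%d) must not exceed min(p, q) = %d", d,
               min(p, q))

  x_center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center)
  Yc <- sweep(Y, 2, y_center)
  x_scale <- rep(1, p); y_scale <- rep(1, q)
  if (scale_x) {
    x_scale <- apply(Xc, 2, stats::sd); x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2, x_scale, `/`)
  }
  if (scale_y) {
    y_scale <- apply(Yc, 2, stats::sd); y_scale[y_scale == 0] <- 1
    Yc <- sweep(Yc, 2, y_scale, `/`)
  }

  Cxx <- crossprod(Xc) / (n - 1)
  Cyy <- crossprod(Yc) / (n - 1)
  Cxy <- crossprod(Xc, Yc) / (n - 1)

  Rxi <- inv_sqrt_sym(Cxx, l1, "chemical")
  Ryi <- inv_sqrt_sym(Cyy, l2, "biological")
  sv <- svd(Rxi %*% Cxy %*% Ryi, nu = d, nv = d)

  W <- Rxi %*% sv$u
  V <- Ryi %*% sv$v

  cv <- Xc %*% W
  bv <- Yc %*% V
  # unit-variance training variates
  sd_cv <- apply(cv, 2, stats::sd); sd_cv[sd_cv == 0] <- 1
  sd_bv <- apply(bv, 2, stats::sd); sd_bv[sd_bv == 0] <- 1
  W <- sweep(W, 2, sd_cv, `/`); cv <- sweep(cv, 2, sd_cv, `/`)
  V <- sweep(V, 2, sd_bv, `/`); bv <- sweep(bv, 2, sd_bv, `/`)

  # deterministic sign: largest |entry| of each chemical weight positive
  for (s in seq_len(d)) {
    i <- which.max(abs(W[, s]))
    if (W[i, s] < 0) {
      W[, s] <- -W[, s]; cv[, s] <- -cv[, s]
      V[, s] <- -V[, s]; bv[, s] <- -bv[, s]
    }
  }

  correlations <- vapply(seq_len(d), function(s) {
    if (stats::sd(cv[, s]) == 0 || stats::sd(bv[, s]) == 0) return(0)
    stats::cor(cv[, s], bv[, s])
  }, numeric(1))

  # under ridge the sample correlation of a variate pair can invert the
  # penalized-objective ordering; reports are ordered by correlation
  pen <- sv$d[seq_len(d)]
  ord <- order(-correlations, -pen)
  W <- W[, ord, drop = FALSE]; V <- V[, ord, drop = FALSE]
  cv <- cv[, ord, drop = FALSE]; bv <- bv[, ord, drop = FALSE]
  correlations <- correlations[ord]; pen <- pen[ord]

  dimnames(W) <- list(colnames(X), paste0("comp_", seq_len(d)))
  dimnames(V) <- list(colnames(Y), paste0("comp_", seq_len(d)))
  dimnames(cv) <- list(rownames(X), colnames(W))
  dimnames(bv) <- list(rownames(X), colnames(W))

  structure(list(
    chem_weights = W, bio_weights = V,
    correlations = pmin(1, pmax(0, correlations)),
    penalized = pmin(1, pmax(0, pen)),
    chem_variates = cv, bio_variates = bv,
    l1 = l1, l2 = l2,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    scale_x = scale_x, scale_y = scale_y,
    n = n, perm_pvalues = NULL, perm_pvalues_raw = NULL,
    schema_version = "1.0"
  ), class = "rcca_model")
}

#' @export
print.rcca_model <- function(x, ...) {
  cat(sprintf("rcca_model: %d components, n = %d, l1 = %g, l2 = %g\n",
              ncol(x$chem_weights), x$n, x$l1, x$l2))
  cat("correlations:",
      paste(format(x$correlations, digits = 3), collapse = ", "), "\n")
  if (!is.null(x$perm_pvalues))
    cat("permutation p:",
        paste(format(x$perm_pvalues, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Project new data onto fitted components
#'
#' Applies the stored centering/scaling and weight matrices. Either view may
#' be `NULL` to project only one space.
#'
#' @param model A fitted `rcca_model`.
#' @param Xnew,Ynew Matrices with the training column names (order may
#'   differ; columns are matched by name when named).
#' @return List with `chem_variates` and/or `bio_variates`.
#' @export
project_rcca <- function(model, Xnew = NULL, Ynew = NULL) {
  out <- list()
  if (!is.null(Xnew)) {
    Xnew <- as.matrix(Xnew)
    if (!is.null(colnames(Xnew))) {
      if (!setequal(colnames(Xnew), names(model$x_center)))
        stop_input("Xnew column names do not match the training descriptors")
      Xnew <- Xnew[, names(model$x_center), drop = FALSE]
    } else if (ncol(Xnew) != length(model$x_center)) {
      stop_input("Xnew has %d columns; expected %d", ncol(Xnew),
                 length(model$x_center))
    }
    Xc <- sweep(sweep(Xnew, 2, model$x_center), 2, model$x_scale, `/`)
    out$chem_variates <- Xc %*% model$chem_weights
  }
  if (!is.null(Ynew)) {
    Ynew <- as.matrix(Ynew)
    if (!is.null(colnames(Ynew))) {
      if (!setequal(colnames(Ynew), names(model$y_center)))
        stop_input("Ynew column names do not match the training gene sets")
      Ynew <- Ynew[, names(model$y_center), drop = FALSE]
    } else if (ncol(Ynew) != length(model$y_center)) {
      stop_input("Ynew has %d columns; expected %d", ncol(Ynew),
                 length(model$y_center))
    }
    Yc <- sweep(sweep(Ynew, 2, model$y_center), 2, model$y_scale, `/`)
    out$bio_variates <- Yc %*% model$bio_weights
  }
  out
}

#' Select ridge penalties by cross-validated retrieval performance
#'
#' For every grid point, fits the model on the training folds, projects all
#' compounds, and scores mean average precision of retrieving functionally
#' similar compounds in the fused component space (concatenated chemical and
#' biological variates), using the held-out compounds as queries. The grid
#' point with the highest fold-averaged MAP wins; ties prefer smaller `l1`,
#' then smaller `l2`.
#'
#' @param X,Y Aligned data matrices.
#' @param grid Data.frame with columns `l1`, `l2` (or list of pairs).
#' @param folds Number of cross-validation folds (>= 2).
#' @param annotations An [annotation_set()]; compounds without labels are
#'   used for fitting but not scored.
#' @param n_components Components fitted per grid point.
#' @param ks Ranking depths averaged into the CV score.
#' @param seed Seed controlling the fold assignment.
#' @param scale_x,scale_y Passed to [fit_rcca()].
#' @return List: `l1`, `l2`, and `scores` (the grid with fold-averaged MAP).
#' @export
select_regularization <- function(X, Y, grid, folds = 20L, annotations,
                                  n_components = NULL,
                                  ks = c(5L, 10L, 20L), seed = 1L,
                                  scale_x = TRUE, scale_y = FALSE) {
  if (is.list(grid) && !is.data.frame(grid))
    grid <- do.call(rbind, lapply(grid, function(g)
      data.frame(l1 = g[[1]], l2 = g[[2]])))
  if (!is.data.frame(grid) || !all(c("l1", "l2") %in% names(grid)) ||
      nrow(grid) == 0)
    stop_input("`grid` must be a non-empty data.frame with columns l1, l2")
  folds <- check_count(folds, "folds", 2L)
  n <- nrow(X)
  if (folds > n) stop_input("more folds than samples")

  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), n))
  ks <- ks[ks <= n - 2]
  if (!length(ks)) ks <- max(2L, n - 2L)

  labelled <- annotated_compounds(annotations, rownames(X))

  score_point <- function(l1, l2) {
    fold_scores <- vapply(seq_len(folds), function(f) {
      test <- which(fold_of == f)
      if (length(test) == 0 || length(test) >= n - 2) return(NA_real_)
      fit <- fit_rcca(X[-test, , drop = FALSE], Y[-test, , drop = FALSE],
                      l1 = l1, l2 = l2, n_components = n_components,
                      scale_x = scale_x, scale_y = scale_y)
      pr <- project_rcca(fit, X, Y)
      fused <- cbind(pr$chem_variates, pr$bio_variates)
      rownames(fused) <- rownames(X)
      queries <- intersect(rownames(X)[test], labelled)
      if (!length(queries)) return(NA_real_)
      sim <- similarity_matrix(fused)
      curve <- map_curve(sim, annotations, ks = ks, queries = queries)
      mean(curve$map)
    }, numeric(1))
    mean(fold_scores, na.rm = TRUE)
  }

  grid$score <- mapply(score_point, grid$l1, grid$l2)
  ord <- order(-grid$score, grid$l1, grid$l2)
  best <- grid[ord[1], ]
  list(l1 = best$l1, l2 = best$l2, scores = grid)
}

#' Permutation significance of the canonical correlations
#'
#' Breaks the compound correspondence by uniformly permuting the rows of
#' `Y`, refits with the same penalties, and records each component's
#' correlation. The per-component p-value is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`; the uncorrected
#' proportion `#{permuted >= observed} / n_perm` is reported alongside.
#'
#' @param X,Y Aligned data matrices.
#' @param l1,l2 Ridge penalties (typically the CV-selected values).
#' @param n_components Components to test.
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed.
#' @param scale_x,scale_y Passed to [fit_rcca()].
#' @return The fitted `rcca_model` on the unpermuted data with
#'   `perm_pvalues`, `perm_pvalues_raw` and `perm_null` (n_perm x S matrix
#'   of null correlations) filled in.
#' @export
permutation_significance <- function(X, Y, l1 = 0, l2 = 0,
                                     n_components = NULL, n_perm = 1000L,
                                     seed = 1L, scale_x = TRUE,
                                     scale_y = FALSE) {
  n_perm <- check_count(n_perm, "n_perm", 19L)
  model <- fit_rcca(X, Y, l1 = l1, l2 = l2, n_components = n_components,
                    scale_x = scale_x, scale_y = scale_y)
  d <- length(model$correlations)
  set.seed(seed)
  null_corr <- matrix(NA_real_, n_perm, d)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(Y))
    Yp <- Y[perm, , drop = FALSE]
    rownames(Yp) <- rownames(Y)
    fb <- fit_rcca(X, Yp, l1 = l1, l2 = l2, n_components = n_components,
                   scale_x = scale_x, scale_y = scale_y)
    null_corr[b, ] <- fb$correlations
  }
  exceed <- colSums(sweep(null_corr, 2, model$correlations, `>=`))
  model$perm_pvalues <- (1 + exceed) / (n_perm + 1)
  model$perm_pvalues_raw <- exceed / n_perm
  model$perm_null <- null_corr
  model
}

#' Indices of components retained for reporting
#'
#' Components with permutation p-value below `p_threshold`, capped at the
#' `max_components` with the highest correlations (components are already
#' ordered by correlation).
#'
#' @param model A fitted `rcca_model` (with `perm_pvalues` when available;
#'   without them all components are eligible).
#' @param p_threshold Significance threshold.
#' @param max_components Cap on the number retained.
#' @return Integer vector of component indices.
#' @export
retained_components <- function(model, p_threshold = 0.05,
                                max_components = 10L) {
  d <- length(model$correlations)
  idx <- seq_len(d)
  if (!is.null(model$perm_pvalues))
    idx <- idx[model$perm_pvalues < p_threshold]
  utils::head(idx, max_components)
}

#' Split components into sign subcomponents
#'
#' Per component, compounds with positive canonical score form subcomponent
#' A and compounds with negative score subcomponent B; exact zeros belong to
#' neither. The score defaults to the mean of the chemical and biological
#' variates; either single side can be configured instead.
#'
#' @param model A fitted `rcca_model`.
#' @param side One of `"mean"`, `"chem"`, `"bio"`.
#' @return A `component_split` object: `scores` (compounds x S matrix) and
#'   `members`, a per-component list with elements `A` and `B` (compound
#'   ids).
#' @export
split_subcomponents <- function(model, side = c("mean", "chem", "bio")) {
  side <- match.arg(side)
  scores <- switch(side,
                   mean = (model$chem_variates + model$bio_variates) / 2,
                   chem = model$chem_variates,
                   bio = model$bio_variates)
  ids <- rownames(scores)
  if (is.null(ids)) ids <- sprintf("row_%d", seq_len(nrow(scores)))
  members <- lapply(seq_len(ncol(scores)), function(s) {
    list(A = ids[scores[, s] > 0], B = ids[scores[, s] < 0])
  })
  names(members) <- colnames(scores)
  structure(list(scores = scores, members = members, side = side),
            class = "component_split")
}

#' @export
print.component_split <- function(x, ...) {
  sizes <- vapply(x$members, function(m)
    sprintf("%d/%d", length(m$A), length(m$B)), character(1))
  cat("component_split (A/B sizes):",
      paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
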