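## Synthetic data with planted cross-space structure.
##
## The generators emulate the statistical shape of a chemogenomic screen:
## a chemical descriptor table and a bounded gene-set activation matrix that
## share a low-rank latent signal with prescribed canonical correlations,
## batch-structured expression profiles with replicated controls, random
## gene-set collections, and functional labels that co-cluster with the
## latent components.

# Semi-orthogonal loading matrix with near-equal row norms: QR of a
# random-sign matrix. Flat rows keep the emitted columns homoscedastic, so
# the bounded activation squash does not distort the planted subspace.
flat_loadings <- function(p, k) {
  qr.Q(qr(matrix(sample(c(-1, 1), p * k, replace = TRUE) / sqrt(p), p, k)))
}

# Bounded monotone squash built on the Gaussian error function:
# maps real values into (-1, 1), near-linear over the bulk of the data.
squash_bounded <- function(x, scale) {
  2 * stats::pnorm(x / scale) - 1
}

#' Simulate paired descriptor and activation matrices with planted canonical
#' correlations
#'
#' Draws per-compound latent pairs \eqn{(u_s, t_s)} from a bivariate normal
#' with component-wise correlation, maps them into the two observed spaces
#' through fixed orthonormal loadings, adds isotropic Gaussian noise, and
#' squashes the activation side into \eqn{[-1, 1]} with a scaled
#' error-function map. The planted correlations are calibrated to be the
#' *population canonical correlations* of the emitted data: the latent
#' correlation is inflated by \eqn{1 + \sigma^2} to cancel the attenuation
#' caused by the additive noise (exact for orthonormal loadings).
#'
#' @param n Number of compounds.
#' @param p Number of chemical descriptors.
#' @param q Number of gene sets.
#' @param k Number of planted components (`k <= min(p, q)`).
#' @param correlations Vector of `k` planted canonical correlations in
#'   `[0, 1]`, sorted non-increasing.
#' @param noise_sd Standard deviation of the additive noise in both spaces.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param squash_mult Squash scale in units of each activation column's
#'   standard deviation. Large values keep the bounded map near-linear.
#' @param n_confounders Number of space-specific latent factors added to
#'   each space independently (structured variation unrelated to the other
#'   space, e.g. descriptor families without biological consequence or
#'   responses unrelated to chemistry). 0 (default) disables them; when
#'   enabled the planted correlations are mildly attenuated.
#' @param confounder_sd Score standard deviation of the confounder
#'   factors (1 = as strong as the shared signal).
#' @return A list with elements `X` (n x p descriptor matrix), `Y` (n x q
#'   activation matrix, entries in `[-1, 1]`) and `truth`, a `latent_truth`
#'   object recording `latent_scores` (bio side), `latent_scores_chem`,
#'   `latent_common` (the shared mechanism factor both spaces observe),
#'   `chem_loadings`, `bio_loadings` (in emitted coordinates),
#'   `planted_correlations`, `noise_sd` and `seed`.
#' @examples
#' d <- simulate_joint_data(100, 8, 10, 2, c(0.8, 0.5), seed = 1)
#' range(d$Y)
#' @export
simulate_joint_data <- function(n, p, q, k, correlations,
                                noise_sd = 0.1, seed = 1L,
                                squash_mult = 6, n_confounders = 0L,
                                confounder_sd = 1) {
  n <- check_count(n, "n", 2L)
  p <- check_count(p, "p", 1L)
  q <- check_count(q, "q", 1L)
  k <- check_count(k, "k", 1L)
  if (k > min(p, q))
    stop_input("k (%d) must not exceed min(p, q) = %d", k, min(p, q))
  if (length(correlations) != k)
    stop_input("`correlations` must have length k = %d", k)
  if (any(correlations < 0 | correlations > 1) || anyNA(correlations))
    stop_input("`correlations` must lie in [0, 1]")
  if (is.unsorted(rev(correlations)))
    stop_input("`correlations` must be sorted non-increasing")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)

  set.seed(seed)
  # cancel additive-noise attenuation so planted values are the population
  # canonical correlations of (X, Y)
  rho_adj <- pmin(1, correlations * (1 + noise_sd^2))

  # symmetric construction: a common factor z observed with equal noise in
  # both spaces gives corr(u_s, t_s) = rho_adj[s], the same bivariate
  # normal joint as the textbook parameterization, while making z the
  # natural carrier of "shared mechanism" used by simulate_annotations()
  Z <- matrix(stats::rnorm(n * k), n, k)
  E1 <- matrix(stats::rnorm(n * k), n, k)
  E2 <- matrix(stats::rnorm(n * k), n, k)
  a <- sqrt(rho_adj)
  U <- sweep(Z, 2, a, `*`) + sweep(E1, 2, sqrt(1 - rho_adj), `*`)
  Tm <- sweep(Z, 2, a, `*`) + sweep(E2, 2, sqrt(1 - rho_adj), `*`)

  A <- flat_loadings(p, k)
  B <- flat_loadings(q, k)

  X <- U %*% t(A) + noise_sd * matrix(stats::rnorm(n * p), n, p)
  Yraw <- Tm %*% t(B) + noise_sd * matrix(stats::rnorm(n * q), n, q)

  n_confounders <- check_count(n_confounders, "n_confounders", 0L)
  if (n_confounders > 0) {
    Cx <- flat_loadings(p, n_confounders)
    Cy <- flat_loadings(q, n_confounders)
    Gx <- confounder_sd * matrix(stats::rnorm(n * n_confounders), n)
    Gy <- confounder_sd * matrix(stats::rnorm(n * n_confounders), n)
    X <- X + Gx %*% t(Cx)
    Yraw <- Yraw + Gy %*% t(Cy)
  }

  col_sd <- apply(Yraw, 2, stats::sd)
  col_sd[col_sd == 0] <- 1
  sq_scale <- squash_mult * col_sd
  Y <- squash_bounded(sweep(Yraw, 2, sq_scale, `/`), 1)

  ids <- sprintf("cmpd_%03d", seq_len(n))
  dimnames(X) <- list(ids, sprintf("desc_%02d", seq_len(p)))
  dimnames(Y) <- list(ids, sprintf("set_%03d", seq_len(q)))

  truth <- structure(list(
    latent_scores = Tm,
    latent_scores_chem = U,
    latent_common = Z,
    chem_loadings = A,
    bio_loadings = B,
    planted_correlations = correlations,
    noise_sd = noise_sd,
    squash_scale = sq_scale,
    seed = as.integer(seed)
  ), class = "latent_truth")

  list(X = X, Y = Y, truth = truth)
}

#' Simulate gene-level response profiles sharing a latent signal
#'
#' Companion to [simulate_joint_data()]: emits a compounds x genes matrix
#' driven by the same biological latent scores, for benchmarking retrieval in
#' the raw gene space against the gene-set and fused component spaces.
#'
#' @param truth A `latent_truth` object from [simulate_joint_data()].
#' @param n_genes Number of genes.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @param n_confounders Biology-specific latent factors unrelated to the
#'   shared signal (matching the activation space's structured variation).
#' @param confounder_sd Score standard deviation of those factors.
#' @return A compounds x genes numeric matrix.
#' @export
simulate_gene_responses <- function(truth, n_genes, noise_sd = 0.1, seed = 1L,
                                    n_confounders = 0L, confounder_sd = 1) {
  if (!inherits(truth, "latent_truth"))
    stop_input("`truth` must be a latent_truth object")
  n_genes <- check_count(n_genes, "n_genes", 1L)
  set.seed(seed)
  Tm <- truth$latent_scores
  k <- ncol(Tm)
  if (n_genes < k) stop_input("n_genes must be >= number of components")
  G <- flat_loadings(n_genes, k)
  out <- Tm %*% t(G) + noise_sd * matrix(stats::rnorm(nrow(Tm) * n_genes),
                                         nrow(Tm), n_genes)
  n_confounders <- check_count(n_confounders, "n_confounders", 0L)
  if (n_confounders > 0) {
    Cg <- flat_loadings(n_genes, n_confounders)
    Gg <- confounder_sd * matrix(stats::rnorm(nrow(Tm) * n_confounders),
                                 nrow(Tm))
    out <- out + Gg %*% t(Cg)
  }
  dimnames(out) <- list(sprintf("cmpd_%03d", seq_len(nrow(Tm))),
                        sprintf("gene_%04d", seq_len(n_genes)))
  out
}

#' Simulate batch-structured expression profiles with planted effects
#'
#' Emulates the structure of a treatment-versus-control expression compendium:
#' log2-scale baseline profiles per batch, several control replicates per
#' batch, treatment profiles that add a planted effect to a compound-specific
#' gene set, optionally one control per designated batch shifted on all genes
#' (an outlier the control-consolidation step should remove).
#'
#' @param compounds Character vector of compound ids.
#' @param n_genes Number of genes in the universe.
#' @param batches Number of batches; compounds are assigned round-robin.
#' @param controls_per_batch Number of control replicates per batch (>= 1).
#' @param effect_size Log2 shift added to each compound's planted gene set.
#' @param outlier_shift Uniform shift applied to one control in each batch
#'   holding at least three controls (0 disables).
#' @param noise_sd Within-batch measurement noise (log2 scale).
#' @param instances_per_compound Replicated treatment instances per compound
#'   (e.g. cell lines); instance ids are `<compound>_i<j>`.
#' @param de_genes_per_compound Size of each compound's planted gene set
#'   (ignored when `planted_sets` is given).
#' @param planted_sets Optional named list (compound -> character vector of
#'   gene ids from the `gene_%04d` universe) fixing each compound's planted
#'   set.
#' @param seed Integer seed.
#' @return An `expression_batches` object: list of per-batch records
#'   (`batch_id`, `treatments` matrix with instance rows, `compound_ids`,
#'   `instance_ids`, `controls` matrix), plus `gene_ids`, `planted_de`
#'   (compound -> list(genes, effect)) and `outlier_controls`
#'   (batch -> control row index).
#' @export
simulate_expression_batches <- function(compounds, n_genes, batches = 3L,
                                        controls_per_batch = 3L,
                                        effect_size = 2,
                                        outlier_shift = 0,
                                        noise_sd = 0.25,
                                        instances_per_compound = 1L,
                                        de_genes_per_compound = 15L,
                                        planted_sets = NULL,
                                        seed = 1L) {
  if (length(compounds) < 1L) stop_input("`compounds` must be non-empty")
  n_genes <- check_count(n_genes, "n_genes", 1L)
  batches <- check_count(batches, "batches", 1L)
  controls_per_batch <- check_count(controls_per_batch, "controls_per_batch", 1L)
  instances_per_compound <- check_count(instances_per_compound,
                                        "instances_per_compound", 1L)
  de_genes_per_compound <- check_count(de_genes_per_compound,
                                       "de_genes_per_compound", 1L)
  if (de_genes_per_compound > n_genes)
    stop_input("n_genes (%d) is smaller than the planted set size (%d)",
               n_genes, de_genes_per_compound)
  if (!is.finite(effect_size)) stop_input("`effect_size` must be finite")

  set.seed(seed)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  baseline <- stats::rnorm(n_genes, mean = 8, sd = 1)

  batch_of <- rep_len(seq_len(batches), length(compounds))
  planted_de <- stats::setNames(vector("list", length(compounds)), compounds)
  outlier_controls <- integer(0)
  batch_list <- vector("list", batches)

  for (b in seq_len(batches)) {
    members <- compounds[batch_of == b]
    batch_base <- baseline + stats::rnorm(n_genes, sd = 0.3)
    controls <- matrix(stats::rnorm(controls_per_batch * n_genes,
                                    sd = noise_sd),
                       controls_per_batch, n_genes, byrow = FALSE)
    controls <- sweep(controls, 2, batch_base, `+`)
    rownames(controls) <- sprintf("batch%d_ctrl%d", b,
                                  seq_len(controls_per_batch))
    if (outlier_shift != 0 && controls_per_batch >= 3) {
      controls[controls_per_batch, ] <-
        controls[controls_per_batch, ] + outlier_shift
      outlier_controls[as.character(b)] <- controls_per_batch
    }

    inst_ids <- character(0)
    cmpd_ids <- character(0)
    rows <- list()
    for (cm in members) {
      genes <- if (!is.null(planted_sets)) {
        idx <- match(planted_sets[[cm]], gene_ids)
        if (anyNA(idx))
          stop_input("planted set for %s has genes outside the universe", cm)
        sort(idx)
      } else sort(sample.int(n_genes, de_genes_per_compound))
      planted_de[[cm]] <- list(genes = gene_ids[genes], effect = effect_size)
      for (j in seq_len(instances_per_compound)) {
        prof <- batch_base + stats::rnorm(n_genes, sd = noise_sd)
        # later instances respond more weakly, so strongest-instance
        # selection has a deterministic planted answer (instance 1)
        prof[genes] <- prof[genes] + effect_size / j
        rows[[length(rows) + 1L]] <- prof
        inst_ids <- c(inst_ids, sprintf("%s_i%d", cm, j))
        cmpd_ids <- c(cmpd_ids, cm)
      }
    }
    treatments <- if (length(rows)) do.call(rbind, rows) else
      matrix(numeric(0), 0, n_genes)
    rownames(treatments) <- inst_ids
    colnames(treatments) <- gene_ids
    colnames(controls) <- gene_ids
    batch_list[[b]] <- list(batch_id = b, treatments = treatments,
                            compound_ids = cmpd_ids,
                            instance_ids = inst_ids, controls = controls)
  }

  structure(list(batches = batch_list, gene_ids = gene_ids,
                 planted_de = planted_de,
                 outlier_controls = outlier_controls,
                 seed = as.integer(seed)),
            class = "expression_batches")
}

#' Simulate a random gene-set collection
#'
#' Samples `n_sets` gene sets without replacement within each set from a gene
#' universe, with sizes drawn uniformly from `size_range`.
#'
#' @param gene_universe Character vector of gene ids.
#' @param n_sets Number of sets (0 gives an empty collection).
#' @param size_range Length-2 integer vector `(min, max)` of set sizes.
#' @param seed Integer seed.
#' @return A [gene_set_collection()] object.
#' @export
simulate_gene_sets <- function(gene_universe, n_sets,
                               size_range = c(10L, 30L), seed = 1L) {
  if (length(gene_universe) < 1L) stop_input("`gene_universe` is empty")
  n_sets <- check_count(n_sets, "n_sets", 0L)
  if (length(size_range) != 2L || size_range[1] > size_range[2])
    stop_input("`size_range` must be (min, max) with min <= max")
  if (size_range[2] > length(gene_universe))
    stop_input("max set size (%d) exceeds universe size (%d)",
               size_range[2], length(gene_universe))
  set.seed(seed)
  sets <- list()
  if (n_sets > 0) {
    sizes <- if (size_range[1] == size_range[2])
      rep(size_range[1], n_sets)
    else sample(seq.int(size_range[1], size_range[2]), n_sets,
                replace = TRUE)
    sets <- lapply(sizes, function(m)
      gene_universe[sample.int(length(gene_universe), m)])
    names(sets) <- sprintf("set_%03d", seq_len(n_sets))
  }
  gene_set_collection(sets, gene_universe)
}

#' Simulate functional annotations aligned with latent structure
#'
#' Assigns each compound one functional label (emulating a protein target or
#' therapeutic class code). Compounds are clustered on the shared latent
#' mechanism factor (the biological latent scores when no common factor is
#' recorded); with probability `alignment` a compound receives its
#' cluster's label,
#' otherwise a uniformly random label. `alignment = 0` yields labels
#' independent of the planted structure; `alignment = 1` makes latent
#' clusters and label groups coincide.
#'
#' @param compounds Character vector of compound ids (row order must match
#'   the latent scores).
#' @param n_labels Number of distinct labels (> 0 when `alignment > 0`).
#' @param truth A `latent_truth` object.
#' @param alignment Probability in `[0, 1]` of inheriting the latent
#'   cluster's label.
#' @param seed Integer seed.
#' @return An [annotation_set()] with one `(compound, label)` pair per
#'   compound, kind `"class-code"`.
#' @export
simulate_annotations <- function(compounds, n_labels, truth, alignment,
                                 seed = 1L) {
  if (!inherits(truth, "latent_truth"))
    stop_input("`truth` must be a latent_truth object")
  alignment <- check_number(alignment, "alignment", 0, 1)
  if (n_labels == 0 && alignment > 0)
    stop_input("n_labels = 0 is only valid with alignment = 0")
  n_labels <- check_count(n_labels, "n_labels", 1L)
  n <- length(compounds)
  if (nrow(truth$latent_scores) != n)
    stop_input("length(compounds) must match the latent scores")

  set.seed(seed)
  # cluster on the common factor when the generator recorded one (labels
  # emulate mechanisms driving both spaces), else on the biological scores
  scores <- if (!is.null(truth$latent_common)) truth$latent_common else
    truth$latent_scores
  # contiguous quantile bins along the leading latent direction, refined by
  # k-means on all latent columns for k > 1; deterministic given the seed
  if (ncol(scores) == 1L) {
    cluster <- as.integer(cut(rank(scores[, 1], ties.method = "first"),
                              breaks = n_labels, labels = FALSE))
  } else {
    km <- suppressWarnings(stats::kmeans(scores, centers = n_labels,
                                         nstart = 5, iter.max = 50))
    cluster <- km$cluster
  }
  labels <- sprintf("label_%02d", seq_len(n_labels))
  take_cluster <- stats::runif(n) < alignment
  assigned <- ifelse(take_cluster, labels[cluster],
                     labels[sample.int(n_labels, n, replace = TRUE)])
  annotation_set(data.frame(compound = compounds, label = assigned,
                            kind = "class-code",
                            stringsAsFactors = FALSE))
}

#' Construct a two-component benchmark with shared compounds but disjoint
#' gene signals
#'
#' Builds a synthetic study in which two cross-space components recruit an
#' overlapping group of high-scoring compounds while driving disjoint blocks
#' of genes, the situation where component pairs show high compound overlap
#' but near-zero overlap of their differentially expressed genes. Used to
#' exercise the subcomponent-similarity contrast (compound overlap vs
#' Tanimoto of gene lists).
#'
#' @param n Number of compounds.
#' @param n_genes Genes in the universe (two disjoint blocks of
#'   `block_size` genes carry the two signals).
#' @param n_shared Number of compounds given extreme scores on both
#'   components.
#' @param block_size Genes per signal block.
#' @param effect Gene-level effect scale.
#' @param noise_sd Residual noise.
#' @param seed Integer seed.
#' @return List with `X`, `Y` (activation), `responses` (compounds x genes),
#'   `collection` (the tiling gene sets), `truth`, `shared_compounds` and the
#'   per-component signal gene blocks.
#' @export
simulate_shared_compound_data <- function(n = 100L, n_genes = 600L,
                                          n_shared = 10L, block_size = 100L,
                                          effect = 1.5, noise_sd = 0.3,
                                          seed = 1L) {
  n <- check_count(n, "n", 60L)
  set.seed(seed)
  k <- 2L
  # latent scores: a shared group extreme-positive on BOTH components,
  # plus component-specific extreme groups so neither component's top list
  # is exhausted by the shared compounds (the realistic situation where
  # only a handful of the top 20 recur across components)
  t1 <- stats::rnorm(n)
  t2 <- stats::rnorm(n)
  shared <- seq_len(n_shared)
  spec1 <- seq.int(n_shared + 1L, n_shared + 10L)
  spec2 <- seq.int(n_shared + 11L, n_shared + 20L)
  # specialists outrank the shared group, so the top-10 lists driving the
  # differential-expression test stay component-specific while the shared
  # group still enters both top-20 compound lists
  t1[shared] <- 3.0 + stats::rnorm(n_shared, sd = 0.2)
  t2[shared] <- 3.0 + stats::rnorm(n_shared, sd = 0.2)
  t1[spec1] <- 4.0 + stats::rnorm(length(spec1), sd = 0.2)
  t2[spec2] <- 4.0 + stats::rnorm(length(spec2), sd = 0.2)
  # two anti-correlated extreme groups cancel the latent correlation the
  # shared group would otherwise induce, keeping the two planted
  # components identifiable by uncorrelated CCA variates
  half <- n_shared %/% 2L
  anti1 <- seq.int(n_shared + 21L, n_shared + 20L + half)
  anti2 <- seq.int(n_shared + 21L + half, n_shared + 20L + 2L * half)
  t1[anti1] <- 3.0 + stats::rnorm(half, sd = 0.2)
  t2[anti1] <- -3.0 + stats::rnorm(half, sd = 0.2)
  t1[anti2] <- -3.0 + stats::rnorm(half, sd = 0.2)
  t2[anti2] <- 3.0 + stats::rnorm(half, sd = 0.2)
  # distinct cross-space coupling per component pins the component order
  # (equal couplings would leave CCA free to rotate the pair)
  coupling <- c(0.97, 0.8)
  Tm <- cbind(t1, t2)
  U <- sweep(Tm, 2, coupling, `*`) +
    matrix(stats::rnorm(n * k), n, k) %*% diag(sqrt(1 - coupling^2))

  p <- 20L
  A <- flat_loadings(p, k)
  X <- U %*% t(A) + noise_sd * matrix(stats::rnorm(n * p), n, p)

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  block1 <- seq_len(block_size)
  block2 <- seq.int(block_size + 1L, 2L * block_size)
  load1 <- stats::runif(block_size, 0.5, 1)
  load2 <- stats::runif(block_size, 0.5, 1)
  R <- matrix(stats::rnorm(n * n_genes, sd = noise_sd), n, n_genes)
  R[, block1] <- R[, block1] + effect * (t1 %o% load1)
  R[, block2] <- R[, block2] + effect * (t2 %o% load2)
  ids <- sprintf("cmpd_%03d", seq_len(n))
  dimnames(R) <- list(ids, gene_ids)
  rownames(X) <- ids
  colnames(X) <- sprintf("desc_%02d", seq_len(p))

  # gene sets tile the universe in order, so sets align with the blocks
  set_size <- 10L
  n_sets <- n_genes %/% set_size
  sets <- lapply(seq_len(n_sets), function(i)
    gene_ids[seq.int((i - 1L) * set_size + 1L, i * set_size)])
  names(sets) <- sprintf("set_%03d", seq_len(n_sets))
  collection <- gene_set_collection(sets, gene_ids)

  # set-level activation: mean response over the set, squashed to [-1, 1]
  Yraw <- sapply(collection$sets, function(g) rowMeans(R[, g, drop = FALSE]))
  sc <- 6 * apply(Yraw, 2, stats::sd)
  sc[sc == 0] <- 1
  Y <- squash_bounded(sweep(Yraw, 2, sc, `/`), 1)
  dimnames(Y) <- list(ids, names(collection$sets))

  truth <- structure(list(latent_scores = Tm, latent_scores_chem = U,
                          chem_loadings = A, bio_loadings = NULL,
                          planted_correlations = coupling,
                          noise_sd = noise_sd, seed = as.integer(seed)),
                     class = "latent_truth")

  list(X = X, Y = Y, responses = response_matrix(R),
       collection = collection, truth = truth,
       shared_compounds = ids[shared],
       signal_genes = list(component1 = gene_ids[block1],
                           component2 = gene_ids[block2]))
}

#' @export
print.latent_truth <- function(x, ...) {
  cat(sprintf("latent_truth: %d compounds, %d planted components\n",
              nrow(x$latent_scores), ncol(x$latent_scores)))
  cat("planted correlations:",
      paste(format(x$planted_correlations, digits = 3), collapse = ", "), "\n")
  invisible(x)
}
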