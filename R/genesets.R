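## Gene-set activation: enrichment scoring of ranked response profiles and
## the signed q-value transform into [-1, 1].

#' Construct a gene-set collection
#'
#' Stores named gene sets against a gene universe. Genes outside the
#' universe are ignored; sets emptied by the intersection are dropped with a
#' warning.
#'
#' @param sets Named list of character vectors (gene ids).
#' @param universe Character vector of all gene ids.
#' @return A `gene_set_collection` object with elements `sets` and
#'   `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(universe) < 1L) stop_input("gene universe is empty")
  if (anyDuplicated(universe)) stop_input("gene universe has duplicate ids")
  if (length(sets) && is.null(names(sets)))
    stop_input("gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop_input("duplicate gene-set name: %s",
               names(sets)[anyDuplicated(names(sets))])
  trimmed <- lapply(sets, function(g) unique(g[g %in% universe]))
  empty <- lengths(trimmed) == 0
  if (any(empty) && length(sets)) {
    warning(sprintf("dropping %d set(s) disjoint from the universe: %s",
                    sum(empty),
                    paste(utils::head(names(sets)[empty], 5), collapse = ", ")),
            call. = FALSE)
    trimmed <- trimmed[!empty]
  }
  structure(list(sets = trimmed, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

# Weighted running-sum enrichment score for one set, given genes ranked by
# decreasing response. Only hit positions can be extrema, so the running sum
# is evaluated just before and at each hit.
#   hit_pos: positions (in rank order) of the set's genes
#   w:       |response|^exponent of every gene, in rank order
running_sum_es <- function(hit_pos, w, n_genes) {
  m <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  hw <- w[hit_pos]
  total <- sum(hw)
  if (total == 0) { # all-zero weights: fall back to unweighted hits
    hw <- rep(1, m); total <- m
  }
  hit_cum <- cumsum(hw) / total
  miss_before <- (hit_pos - seq_len(m)) / (n_genes - m)
  dev_at <- hit_cum - miss_before          # just after each hit
  dev_pre <- c(0, hit_cum[-m]) - miss_before # just before each hit
  cand <- c(dev_at, dev_pre)
  cand[which.max(abs(cand))]
}

#' Gene-set enrichment scores for one response profile
#'
#' Ranks genes by decreasing response and computes, per gene set, a weighted
#' Kolmogorov-Smirnov running-sum enrichment score (weights are
#' `|response|^exponent`; the score is the most extreme deviation between
#' the weighted cumulative hit fraction and the cumulative miss fraction).
#' The null distribution is obtained by gene-label permutation (random sets
#' of the same size), the score is normalised by the mean null magnitude on
#' its own sign (NES), and FDR q-values are computed from the pooled
#' permutation null of the NES, clipped to `[0, 1]`. This is a
#' self-contained simplified scorer following the standard running-sum
#' formulation; precomputed (set, es, q) tables can be supplied downstream
#' instead via [build_activation_matrix()].
#'
#' @param response Named numeric vector covering the collection's universe.
#' @param collection A [gene_set_collection()].
#' @param n_perm Number of gene-label permutations (>= 10).
#' @param seed Integer seed for the permutation null.
#' @param exponent Weighting exponent on `|response|` (1 = standard
#'   weighting; 0 = classic unweighted statistic).
#' @return A data.frame with one row per set: `set`, `size`, `es`, `nes`,
#'   `p` (permutation p-value, +1-corrected), `q` (FDR), `sign` (+1/-1;
#'   an ES of exactly 0 is assigned +1).
#' @export
enrichment_scores <- function(response, collection, n_perm = 200L,
                              seed = 1L, exponent = 1) {
  if (!inherits(collection, "gene_set_collection"))
    stop_input("`collection` must be a gene_set_collection")
  n_perm <- check_count(n_perm, "n_perm", 10L)
  if (is.null(names(response)))
    stop_input("`response` must be a named vector")
  missing <- setdiff(collection$universe, names(response))
  if (length(missing))
    stop_input("response does not cover the universe (%d genes missing)",
               length(missing))
  response <- response[collection$universe]

  ord <- order_desc_by(response, names(response))
  w <- abs(response[ord])^exponent
  rank_of <- match(collection$universe, names(response)[ord])
  names(rank_of) <- collection$universe
  n_genes <- length(response)

  sets <- collection$sets
  sizes <- lengths(sets)
  es <- vapply(seq_along(sets), function(i) {
    running_sum_es(rank_of[sets[[i]]], w, n_genes)
  }, numeric(1))

  # permutation null, shared across sets of equal size
  set.seed(seed)
  null_by_size <- list()
  for (m in sort(unique(sizes))) {
    null_by_size[[as.character(m)]] <- vapply(seq_len(n_perm), function(b) {
      running_sum_es(sample.int(n_genes, m), w, n_genes)
    }, numeric(1))
  }

  nes <- numeric(length(es)); pval <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nul <- null_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(nul[nul >= 0]); neg_mean <- mean(abs(nul[nul < 0]))
    if (!is.finite(pos_mean) || pos_mean == 0) pos_mean <- 1
    if (!is.finite(neg_mean) || neg_mean == 0) neg_mean <- 1
    nes[i] <- if (es[i] >= 0) es[i] / pos_mean else es[i] / neg_mean
    null_nes[[i]] <- ifelse(nul >= 0, nul / pos_mean, nul / neg_mean)
    same_side <- if (es[i] >= 0) nul[nul >= 0] else nul[nul < 0]
    pval[i] <- (1 + sum(abs(same_side) >= abs(es[i]))) /
      (1 + length(same_side))
  }
  pooled <- unlist(null_nes, use.names = FALSE)

  q <- vapply(seq_along(nes), function(i) {
    v <- nes[i]
    if (v >= 0) {
      num_top <- sum(pooled >= v) / max(1L, sum(pooled >= 0))
      den <- sum(nes >= v) / max(1L, sum(nes >= 0))
    } else {
      num_top <- sum(pooled <= v) / max(1L, sum(pooled < 0))
      den <- sum(nes <= v) / max(1L, sum(nes < 0))
    }
    if (den == 0) return(0)
    min(1, max(0, num_top / den))
  }, numeric(1))

  data.frame(set = names(sets), size = as.integer(sizes), es = es,
             nes = nes, p = pval, q = q,
             sign = ifelse(es >= 0, 1L, -1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed activation from an enrichment q-value
#'
#' Maps an FDR q-value (0 = strongest enrichment) and a direction into a
#' bounded activation value: `sign * (1 - q)`. A q of 0 gives the maximal
#' activation of +/-1; a q of 1 gives 0.
#'
#' @param q Numeric q-values in `[0, 1]`.
#' @param sign Vector of +1/-1 (recycled).
#' @return Numeric activations in `[-1, 1]`.
#' @export
signed_activation <- function(q, sign = 1) {
  if (anyNA(q) || any(q < 0 | q > 1))
    stop_input("q-values must lie in [0, 1]")
  if (any(!sign %in% c(-1, 1)))
    stop_input("sign must be +1 or -1")
  sign * (1 - q)
}

#' Assemble the compounds x gene-sets activation matrix
#'
#' Combines per-compound enrichment results into the bounded activation
#' matrix used as the biological space: entry = `sign * (1 - q)`.
#'
#' @param results Named list of per-compound enrichment data.frames (as from
#'   [enrichment_scores()], or externally computed tables with columns
#'   `set`, `q`, `sign`).
#' @param collection A [gene_set_collection()]; activation columns follow
#'   its set order.
#' @return Numeric matrix (compounds x sets) with entries in `[-1, 1]`.
#' @export
build_activation_matrix <- function(results, collection) {
  if (!length(results) || is.null(names(results)))
    stop_input("`results` must be a named list of enrichment tables")
  set_names <- names(collection$sets)
  mat <- matrix(NA_real_, length(results), length(set_names),
                dimnames = list(names(results), set_names))
  for (cm in names(results)) {
    r <- results[[cm]]
    if (!all(c("set", "q", "sign") %in% names(r)))
      stop_input("enrichment table for %s lacks set/q/sign columns", cm)
    if (!setequal(r$set, set_names))
      stop_input("set names for compound %s differ from the collection", cm)
    idx <- match(set_names, r$set)
    mat[cm, ] <- signed_activation(r$q[idx], r$sign[idx])
  }
  mat
}

#' Activation profiles for every compound of a response matrix
#'
#' Convenience wrapper running [enrichment_scores()] per compound and
#' assembling the activation matrix.
#'
#' @param responses A [response_matrix()] (one row per compound).
#' @param collection A [gene_set_collection()].
#' @param n_perm Permutations per compound.
#' @param seed Global seed (fanned out per compound).
#' @param exponent Running-sum weighting exponent.
#' @return Compounds x sets activation matrix.
#' @export
compute_activation <- function(responses, collection, n_perm = 100L,
                               seed = 1L, exponent = 1) {
  vals <- responses$values
  results <- lapply(seq_len(nrow(vals)), function(i) {
    enrichment_scores(vals[i, ], collection, n_perm = n_perm,
                      seed = child_seed(seed, i), exponent = exponent)
  })
  names(results) <- rownames(vals)
  build_activation_matrix(results, collection)
}
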