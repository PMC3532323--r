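## Retrieval validation: rank compounds by similarity in a representation
## and score retrieval of functionally similar compounds by mean average
## precision.

#' Construct an annotation set
#'
#' Stores the compound -> functional-label relation (protein targets,
#' therapeutic class codes) used for retrieval relevance and enrichment.
#' Duplicate pairs are removed.
#'
#' @param pairs Data.frame with columns `compound`, `label` and optionally
#'   `kind` (defaults to `"target"`).
#' @return An `annotation_set` object wrapping the de-duplicated relation.
#' @export
annotation_set <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("compound", "label") %in% names(pairs)))
    stop_input("`pairs` must be a data.frame with columns compound, label")
  if (!"kind" %in% names(pairs)) pairs$kind <- "target"
  pairs <- unique(pairs[, c("compound", "label", "kind")])
  pairs$compound <- as.character(pairs$compound)
  pairs$label <- as.character(pairs$label)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d pairs, %d compounds, %d labels\n",
              nrow(x$pairs), length(unique(x$pairs$compound)),
              length(unique(x$pairs$label))))
  invisible(x)
}

# Compounds eligible as queries: annotated and sharing >= 1 label with at
# least one other compound in `universe`.
annotated_compounds <- function(annotations, universe) {
  if (!inherits(annotations, "annotation_set"))
    stop_input("`annotations` must be an annotation_set")
  pr <- annotations$pairs[annotations$pairs$compound %in% universe, ]
  if (!nrow(pr)) return(character(0))
  by_label <- split(pr$compound, pr$label)
  shared <- unlist(by_label[lengths(lapply(by_label, unique)) >= 2])
  sort(unique(shared))
}

# Relevant set for a query: compounds sharing >= 1 label.
relevant_for <- function(annotations, query, universe) {
  pr <- annotations$pairs
  labs <- pr$label[pr$compound == query]
  rel <- unique(pr$compound[pr$label %in% labs])
  setdiff(intersect(rel, universe), query)
}

#' Pairwise compound similarities in a representation
#'
#' Pearson correlation between the compounds' feature vectors. Rows with
#' zero variance get similarity 0 to every other compound and are flagged.
#'
#' @param representation Numeric matrix, compounds x features (>= 2 of
#'   each).
#' @return Symmetric similarity matrix with unit diagonal; attribute
#'   `zero_variance` lists flagged compound ids.
#' @export
similarity_matrix <- function(representation) {
  representation <- as.matrix(representation)
  if (nrow(representation) < 2 || ncol(representation) < 2)
    stop_input("need at least 2 compounds and 2 features")
  rs <- apply(representation, 1, stats::sd)
  flagged <- rownames(representation)[rs == 0]
  sim <- suppressWarnings(stats::cor(t(representation)))
  sim[is.na(sim)] <- 0
  if (length(flagged)) {
    sim[rs == 0, ] <- 0
    sim[, rs == 0] <- 0
  }
  diag(sim) <- 1
  attr(sim, "zero_variance") <- flagged
  sim
}

#' Average precision at depth k
#'
#' `AP@k` = mean, over the relevant items found in the top `k` of the
#' ranking, of the precision at each relevant item's rank; 0 when no
#' relevant item is ranked in the top `k`. The query itself must not appear
#' in its ranking.
#'
#' @param ranking Character vector, compounds ordered by decreasing
#'   similarity to the query.
#' @param relevant Character vector of relevant compounds (non-empty).
#' @param k Ranking depth (`k <= length(ranking)`).
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(ranking, relevant, k) {
  if (!length(relevant)) stop_input("`relevant` must be non-empty")
  k <- check_count(k, "k", 1L)
  if (k > length(ranking))
    stop_input("k (%d) exceeds ranking length (%d)", k, length(ranking))
  hits <- ranking[seq_len(k)] %in% relevant
  if (!any(hits)) return(0)
  prec_at <- cumsum(hits)[hits] / which(hits)
  mean(prec_at)
}

#' Mean average precision curve over ranking depths
#'
#' Uses every eligible annotated compound once as a query, ranks all other
#' compounds by similarity (ties broken by compound id), and reports mean
#' and standard error of the average precision per depth `k`. Relevance =
#' sharing at least one label with the query.
#'
#' @param similarities Symmetric similarity matrix with compound dimnames.
#' @param annotations An [annotation_set()].
#' @param ks Integer vector of depths (default `seq(5, 100, by = 5)`).
#' @param queries Optional subset of query compounds (still filtered to
#'   eligible ones).
#' @return A `retrieval_curve` data.frame: `k`, `map`, `sem`, `n_queries`.
#' @export
map_curve <- function(similarities, annotations, ks = seq(5L, 100L, by = 5L),
                      queries = NULL) {
  ids <- rownames(similarities)
  if (is.null(ids)) stop_input("similarity matrix must carry compound ids")
  eligible <- annotated_compounds(annotations, ids)
  if (!is.null(queries)) eligible <- intersect(eligible, queries)
  if (!length(eligible)) stop_input("no annotated compounds to query")
  ks <- as.integer(ks[ks <= length(ids) - 1])
  if (!length(ks)) stop_input("all ks exceed the number of candidates")
  if (is.unsorted(ks, strictly = TRUE))
    stop_input("`ks` must be strictly increasing")

  ap <- matrix(NA_real_, length(eligible), length(ks),
               dimnames = list(eligible, ks))
  for (qd in eligible) {
    others <- setdiff(ids, qd)
    sims <- similarities[qd, others]
    ranking <- others[order_desc_by(sims, others)]
    rel <- relevant_for(annotations, qd, ids)
    for (j in seq_along(ks))
      ap[qd, j] <- average_precision(ranking, rel, ks[j])
  }
  out <- data.frame(
    k = ks,
    map = colMeans(ap),
    sem = apply(ap, 2, stats::sd) / sqrt(nrow(ap)),
    n_queries = nrow(ap)
  )
  class(out) <- c("retrieval_curve", "data.frame")
  out
}

# Exact expected AP@k of a uniformly random ranking of N items of which R
# are relevant. Conditioning on h hits in the top k, hit positions are a
# uniform h-subset of 1..k and the expected hit index at position i is
# 1 + (h-1)(i-1)/(k-1), giving a closed form; the hit count h is
# hypergeometric.
expected_ap_random <- function(N, R, k) {
  if (R == 0) return(0)
  hs <- seq_len(min(k, R))
  ph <- stats::dhyper(hs, R, N - R, k)
  i <- seq_len(k)
  base <- sum(1 / i) / k
  slope <- if (k > 1) sum((i - 1) / i) / (k * (k - 1)) else 0
  inner <- base + (hs - 1) * slope
  sum(ph * inner)
}

#' Expected retrieval performance of a random ranking
#'
#' Analytic baseline for a retrieval curve: the exact expected average
#' precision at depth `k` of a uniformly random ranking, averaged over the
#' eligible queries (each with its own number of relevant compounds). Note
#' this exceeds the mean relevant fraction at small `k`, because average
#' precision is evaluated only at ranks that hold a relevant item.
#'
#' @param annotations An [annotation_set()].
#' @param universe Compound ids in the ranked pool.
#' @param ks Depths (default a single pooled value over `ks = NULL` is not
#'   allowed; give the depths of the curve being compared).
#' @return Numeric vector of expected MAP values, one per depth.
#' @export
random_baseline_map <- function(annotations, universe,
                                ks = seq(5L, 100L, by = 5L)) {
  eligible <- annotated_compounds(annotations, universe)
  if (!length(eligible)) stop_input("no annotated compounds")
  ks <- as.integer(ks[ks <= length(universe) - 1])
  rel_counts <- vapply(eligible, function(qd)
    length(relevant_for(annotations, qd, universe)), integer(1))
  vapply(ks, function(k)
    mean(vapply(rel_counts, function(R)
      expected_ap_random(length(universe) - 1L, R, k), numeric(1))),
    numeric(1))
}

#' Retrieval comparison across representations
#'
#' Computes retrieval curves for the fused CCA component space
#' (concatenated chemical and biological variates of the retained
#' components), the chemical descriptor space, the gene-set activation
#' space, and the gene-level response space.
#'
#' @param X Descriptor matrix.
#' @param Y_genesets Activation matrix.
#' @param Y_genes Gene-level response matrix (or `NULL` to skip).
#' @param model A fitted `rcca_model`.
#' @param annotations An [annotation_set()].
#' @param ks Ranking depths.
#' @param components Components fused for the CCA space (default
#'   [retained_components()]).
#' @return Named list of `retrieval_curve` objects (`cca`, `chem`,
#'   `geneset`, and `gene` when supplied).
#' @export
compare_spaces <- function(X, Y_genesets, Y_genes = NULL, model,
                           annotations, ks = seq(5L, 100L, by = 5L),
                           components = NULL) {
  if (is.null(components)) components <- retained_components(model)
  if (!length(components)) stop_input("no components retained")
  fused <- cbind(model$chem_variates[, components, drop = FALSE],
                 model$bio_variates[, components, drop = FALSE])
  rownames(fused) <- rownames(X)
  curves <- list(
    cca = map_curve(similarity_matrix(fused), annotations, ks),
    chem = map_curve(similarity_matrix(X), annotations, ks),
    geneset = map_curve(similarity_matrix(Y_genesets), annotations, ks)
  )
  if (!is.null(Y_genes))
    curves$gene <- map_curve(similarity_matrix(Y_genes), annotations, ks)
  for (nm in names(curves)) attr(curves[[nm]], "space") <- nm
  curves
}
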