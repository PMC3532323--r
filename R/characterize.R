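## Per-component characterization: top gene sets and compounds, moderated
## t-test gene lists, hypergeometric term enrichment, component-pair
## similarity, and target-sharing resampling.

#' Gene sets most associated with a component
#'
#' Ranks gene sets by the absolute Pearson correlation between the set's
#' activation column and the component's biological variate; the signed
#' correlation is reported. Constant columns get association 0. Ties in
#' absolute correlation are broken by set name.
#'
#' @param model A fitted `rcca_model`.
#' @param Y Activation matrix used in the fit.
#' @param component Component index.
#' @param k Number of sets to return (default 10).
#' @return Data.frame `set`, `association`, ordered by decreasing
#'   `|association|`.
#' @export
top_gene_sets <- function(model, Y, component, k = 10L) {
  k <- check_count(k, "k", 1L)
  component <- check_count(component, "component", 1L)
  variate <- model$bio_variates[, component]
  assoc <- suppressWarnings(as.vector(stats::cor(Y, variate)))
  assoc[is.na(assoc)] <- 0
  ord <- order(-abs(assoc), colnames(Y), method = "radix")
  utils::head(data.frame(set = colnames(Y)[ord], association = assoc[ord],
                         row.names = NULL, stringsAsFactors = FALSE), k)
}

#' Highest-scoring compounds of a subcomponent
#'
#' Members of the requested side ranked by decreasing absolute canonical
#' score; at most `k` returned.
#'
#' @param split A [split_subcomponents()] result.
#' @param component Component index.
#' @param side `"A"` (positive scores) or `"B"` (negative).
#' @param k Number of compounds (default 20).
#' @return Data.frame `compound`, `score`.
#' @export
top_compounds <- function(split, component, side = c("A", "B"), k = 20L) {
  side <- match.arg(side)
  k <- check_count(k, "k", 1L)
  members <- split$members[[component]][[side]]
  sc <- split$scores[members, component]
  ord <- order_desc_by(abs(sc), members)
  utils::head(data.frame(compound = members[ord], score = sc[ord],
                         row.names = NULL, stringsAsFactors = FALSE), k)
}

#' Moderated one-sample t-test with a pooled background variance
#'
#' Tests mean 0 with the moderated variance
#' `s2_tilde = (prior_df * background_var + (n - 1) * s2) / (prior_df + n - 1)`
#' and `t = mean / (s_tilde / sqrt(n))`, two-sided p from a t distribution
#' with `prior_df + n - 1` degrees of freedom. With `prior_df = 0` this is
#' exactly the ordinary one-sample Student t-test; with a positive prior
#' the statistic stays finite for genes with zero sample variance, and
#' under the hierarchical model (gene variances drawn from a scaled
#' inverse chi-squared prior with `prior_df` degrees of freedom and scale
#' `background_var`) the statistic is exactly t-distributed.
#'
#' @param values Numeric vector of response samples for one gene (n >= 2).
#' @param background_var Background (prior) variance, e.g. pooled from
#'   genes with similar mean expression.
#' @param prior_df Prior degrees of freedom (>= 0).
#' @return List `t`, `p`, `df`.
#' @export
regularized_t <- function(values, background_var, prior_df = 10) {
  n <- length(values)
  if (n < 2) stop_input("need at least 2 samples per gene")
  if (prior_df < 0) stop_input("prior_df must be >= 0")
  df <- prior_df + n - 1
  m <- mean(values)
  s2 <- stats::var(values)
  s2_tilde <- (prior_df * background_var + (n - 1) * s2) / df
  if (s2_tilde <= 0) s2_tilde <- .Machine$double.eps
  t_stat <- m / (sqrt(s2_tilde) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = df), df = df)
}

# Background variances from a sliding window of `window` genes ordered by
# mean response: local pooling across genes of similar expression level.
windowed_background_var <- function(means, vars, window = 101L) {
  g <- length(means)
  window <- min(window, g)
  half <- window %/% 2L
  ord <- order(means, method = "radix")
  out <- numeric(g)
  cs <- cumsum(vars[ord])
  for (i in seq_len(g)) {
    lo <- max(1L, i - half); hi <- min(g, i + half)
    out[ord[i]] <- (cs[hi] - if (lo > 1) cs[lo - 1] else 0) / (hi - lo + 1)
  }
  out
}

#' Moderated t-tests for a response submatrix
#'
#' Applies [regularized_t()] to every gene (column) of a compounds x genes
#' response matrix, with background variances pooled over a sliding window
#' of genes ordered by mean response.
#'
#' @param values Numeric matrix, compounds x genes.
#' @param prior_df Prior degrees of freedom.
#' @param window Sliding-window width (genes).
#' @return Data.frame `gene`, `mean`, `t`, `p`.
#' @export
moderated_t_table <- function(values, prior_df = 10, window = 101L) {
  if (nrow(values) < 2) stop_input("need at least 2 compounds")
  means <- colMeans(values)
  vars <- apply(values, 2, stats::var)
  bg <- windowed_background_var(means, vars, window)
  n <- nrow(values)
  df <- prior_df + n - 1
  s2_tilde <- (prior_df * bg + (n - 1) * vars) / df
  s2_tilde[s2_tilde <= 0] <- .Machine$double.eps
  t_stat <- means / sqrt(s2_tilde / n)
  data.frame(gene = colnames(values), mean = means, t = t_stat,
             p = 2 * stats::pt(-abs(t_stat), df = df),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Significantly responding genes of a subcomponent
#'
#' Candidate genes are the union of the genes in the top `n_sets` positively
#' and top `n_sets` negatively associated gene sets of the component. Their
#' differential expression across the subcomponent's top `n_compounds`
#' compounds (by absolute score) is tested with the moderated t-test; genes
#' with `p < p_threshold` are returned ranked by p, with the leading
#' `n_report` flagged for export.
#'
#' @param model A fitted `rcca_model`.
#' @param split A [split_subcomponents()] result.
#' @param responses A [response_matrix()] (one row per compound).
#' @param Y Activation matrix.
#' @param collection The [gene_set_collection()] behind `Y`.
#' @param component Component index.
#' @param side `"A"` or `"B"`.
#' @param n_sets Sets taken per direction (default 20).
#' @param n_compounds Compounds tested (default 10; fewer with a warning
#'   when the side is smaller).
#' @param p_threshold Significance threshold on the raw p-value.
#' @param n_report Length of the exported top list (default 30).
#' @param prior_df,window Moderated t-test parameters.
#' @return Data.frame `gene`, `mean`, `t`, `p` for significant genes
#'   (ranked by p); attribute `top` holds the first `n_report` gene ids,
#'   attribute `candidates` the tested gene ids.
#' @export
component_de_genes <- function(model, split, responses, Y, collection,
                               component, side = "A", n_sets = 20L,
                               n_compounds = 10L, p_threshold = 0.05,
                               n_report = 30L, prior_df = 10,
                               window = 101L) {
  assoc <- suppressWarnings(as.vector(stats::cor(Y,
    model$bio_variates[, component])))
  assoc[is.na(assoc)] <- 0
  names(assoc) <- colnames(Y)
  pos <- names(utils::head(sort(assoc[assoc > 0], decreasing = TRUE), n_sets))
  neg <- names(utils::head(sort(assoc[assoc < 0]), n_sets))
  candidates <- sort(unique(unlist(collection$sets[c(pos, neg)])))
  candidates <- intersect(candidates, colnames(responses$values))
  if (!length(candidates)) stop_input("no candidate genes found")

  top <- top_compounds(split, component, side, k = n_compounds)
  if (nrow(top) < n_compounds)
    warning(sprintf("subcomponent %d%s has only %d compounds; using all",
                    component, side, nrow(top)), call. = FALSE)
  if (nrow(top) < 2)
    stop_input("subcomponent %d%s has fewer than 2 compounds", component,
               side)
  sub <- responses$values[top$compound, candidates, drop = FALSE]
  tests <- moderated_t_table(sub, prior_df = prior_df, window = window)
  sig <- tests[tests$p < p_threshold, ]
  sig <- sig[order(sig$p, sig$gene, method = "radix"), ]
  rownames(sig) <- NULL
  attr(sig, "top") <- utils::head(sig$gene, n_report)
  attr(sig, "candidates") <- candidates
  sig
}

#' Hypergeometric term over-representation
#'
#' For each term (gene set in a generic term collection), the upper-tail
#' hypergeometric probability of observing at least the overlap between the
#' gene list and the term, drawing `|list|` genes from the universe. Terms
#' are ranked by ascending p; raw p-values are reported.
#'
#' @param gene_list Character vector (subset of the universe).
#' @param term_collection A [gene_set_collection()] of terms.
#' @param universe Character vector of background genes (defaults to the
#'   collection's universe).
#' @return Data.frame `term`, `overlap`, `size`, `p`, ascending in p (ties
#'   by term name).
#' @export
term_enrichment <- function(gene_list, term_collection, universe = NULL) {
  if (is.null(universe)) universe <- term_collection$universe
  if (!all(gene_list %in% universe))
    stop_input("gene_list contains genes outside the universe")
  gene_list <- unique(gene_list)
  n_u <- length(universe)
  n_l <- length(gene_list)
  rows <- lapply(names(term_collection$sets), function(tm) {
    genes <- intersect(term_collection$sets[[tm]], universe)
    ov <- length(intersect(genes, gene_list))
    p <- if (ov == 0) 1 else
      stats::phyper(ov - 1, length(genes), n_u - length(genes), n_l,
                    lower.tail = FALSE)
    data.frame(term = tm, overlap = ov, size = length(genes), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Tanimoto similarity of two id sets
#'
#' `|a intersect b| / |a union b|`; 0 when both sets are empty.
#'
#' @param a,b Character vectors (treated as sets).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Target-sharing enrichment of a compound list
#'
#' Statistic: number of targets annotated to at least two compounds of the
#' list (alternatively, the number of compound pairs sharing a target). The
#' null distribution resamples lists of the same size from the annotated
#' compound pool; `p = (1 + #{draws >= observed}) / (n_draws + 1)`.
#'
#' @param compounds Compound ids of the subcomponent list (>= 2).
#' @param annotations An [annotation_set()].
#' @param n_draws Random draws (default 1000).
#' @param seed Integer seed.
#' @param statistic `"targets_shared"` (default) or `"pairs_sharing"`.
#' @return List: `shared_targets` (ids with their list multiplicity),
#'   `statistic`, `p`, `null` (the resampled statistics).
#' @export
target_enrichment <- function(compounds, annotations, n_draws = 1000L,
                              seed = 1L,
                              statistic = c("targets_shared",
                                            "pairs_sharing")) {
  statistic <- match.arg(statistic)
  if (length(compounds) < 2) stop_input("need at least 2 compounds")
  n_draws <- check_count(n_draws, "n_draws", 1L)
  pr <- annotations$pairs
  pool <- sort(unique(pr$compound))

  stat_of <- function(ids) {
    sub <- pr[pr$compound %in% ids, ]
    cnt <- vapply(split(sub$compound, sub$label),
                  function(x) length(unique(x)), integer(1))
    if (statistic == "targets_shared") sum(cnt >= 2)
    else sum(choose(cnt, 2))
  }

  observed <- stat_of(compounds)
  sub <- pr[pr$compound %in% compounds, ]
  cnt <- vapply(split(sub$compound, sub$label),
                function(x) length(unique(x)), integer(1))
  shared <- cnt[cnt >= 2]

  set.seed(seed)
  null <- vapply(seq_len(n_draws), function(b)
    stat_of(sample(pool, min(length(compounds), length(pool)))),
    numeric(1))
  list(shared_targets = shared, statistic = observed,
       p = (1 + sum(null >= observed)) / (n_draws + 1), null = null)
}

#' Full report for one subcomponent
#'
#' Bundles top compounds, top gene sets, significant genes, term
#' enrichment and (when annotations are given) target enrichment for one
#' component side.
#'
#' @param model,split,responses,Y,collection See [component_de_genes()].
#' @param component Component index.
#' @param side `"A"` or `"B"`.
#' @param annotations Optional [annotation_set()].
#' @param terms Optional term [gene_set_collection()] for enrichment
#'   (defaults to `collection`).
#' @param k_compounds,k_sets,n_report Sizes of the exported lists.
#' @param seed Seed for the target resampling.
#' @param ... Passed to [component_de_genes()].
#' @return A `subcomponent_report` list.
#' @export
subcomponent_report <- function(model, split, responses, Y, collection,
                                component, side = "A", annotations = NULL,
                                terms = NULL, k_compounds = 20L,
                                k_sets = 10L, n_report = 30L, seed = 1L,
                                ...) {
  if (is.null(terms)) terms <- collection
  top_cmpd <- top_compounds(split, component, side, k = k_compounds)
  sets <- top_gene_sets(model, Y, component, k = k_sets)
  genes <- component_de_genes(model, split, responses, Y, collection,
                              component, side, n_report = n_report, ...)
  enr <- if (nrow(genes)) {
    gl <- intersect(attr(genes, "top"), terms$universe)
    if (length(gl)) term_enrichment(gl, terms) else NULL
  } else NULL
  tgt <- if (!is.null(annotations) && nrow(top_cmpd) >= 2)
    target_enrichment(top_cmpd$compound, annotations, seed = seed) else NULL
  structure(list(component = component, side = side,
                 top_compounds = top_cmpd, top_gene_sets = sets,
                 significant_genes = genes,
                 top_genes = attr(genes, "top"),
                 term_enrichment = enr, target_enrichment = tgt),
            class = "subcomponent_report")
}

#' Component-pair similarity matrices
#'
#' For every pair of subcomponent reports: biological similarity = Tanimoto
#' overlap of the top significant gene lists; compound overlap = size of the
#' intersection of the top compound lists.
#'
#' @param reports List of [subcomponent_report()] objects.
#' @return List of two symmetric matrices: `biological` (Tanimoto) and
#'   `compound_overlap` (counts), labelled `<component><side>`.
#' @export
subcomponent_similarity <- function(reports) {
  labels <- vapply(reports, function(r)
    paste0(r$component, r$side), character(1))
  m <- length(reports)
  bio <- matrix(0, m, m, dimnames = list(labels, labels))
  ov <- matrix(0L, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    bio[i, j] <- tanimoto(reports[[i]]$top_genes, reports[[j]]$top_genes)
    ov[i, j] <- length(intersect(reports[[i]]$top_compounds$compound,
                                 reports[[j]]$top_compounds$compound))
  }
  list(biological = bio, compound_overlap = ov)
}

#' Association table linking descriptors, components and gene sets
#'
#' Long-format table behind the tripartite component visualization:
#' descriptor rows carry subcomponent-specific association weights (mean
#' descriptor value of the side's compounds, standardized scale), gene-set
#' rows carry the component-level association (correlation with the
#' biological variate) once per component (side `"AB"`). All descriptors
#' are retained; gene sets are cut at `k_sets` per component.
#'
#' @param model A fitted `rcca_model`.
#' @param split A [split_subcomponents()] result.
#' @param Y Activation matrix.
#' @param X Descriptor matrix.
#' @param components Components to include (default
#'   [retained_components()]).
#' @param k_sets Gene sets per component (default 10).
#' @return Data.frame `component`, `side`, `kind`
#'   (`descriptor`/`gene-set`), `element`, `weight`.
#' @export
eye_diagram_table <- function(model, split, Y, X, components = NULL,
                              k_sets = 10L) {
  if (is.null(components)) components <- retained_components(model)
  Xs <- scale(X, center = model$x_center, scale = model$x_scale)
  rows <- list()
  for (s in components) {
    for (side in c("A", "B")) {
      members <- split$members[[s]][[side]]
      if (length(members)) {
        act <- colMeans(Xs[members, , drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
          component = s, side = side, kind = "descriptor",
          element = colnames(X), weight = as.numeric(act),
          stringsAsFactors = FALSE)
      }
    }
    # gene sets carry the overall component association, one row per set
    sets <- top_gene_sets(model, Y, s, k = k_sets)
    rows[[length(rows) + 1L]] <- data.frame(
      component = s, side = "AB", kind = "gene-set",
      element = sets$set, weight = sets$association,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
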