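# Independent brute-force oracles used to pin expected values.

# Average precision by direct definition: walk the ranking, at every rank
# holding a relevant item record precision-so-far, average those within k.
oracle_ap <- function(ranking, relevant, k) {
  found <- 0
  precs <- c()
  for (i in seq_len(k)) {
    if (ranking[i] %in% relevant) {
      found <- found + 1
      precs <- c(precs, found / i)
    }
  }
  if (!length(precs)) 0 else mean(precs)
}

# All permutations of a vector (exhaustive).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Running-sum enrichment score by full prefix scan: evaluate the deviation
# between weighted hit fraction and miss fraction after every position and
# take the most extreme value (checking the zero start as well).
oracle_es <- function(response, genes_in_set, exponent = 1) {
  ord <- order(-response, names(response), method = "radix")
  ranked <- names(response)[ord]
  w <- abs(response[ord])^exponent
  hit <- ranked %in% genes_in_set
  total_w <- sum(w[hit])
  if (total_w == 0) { w <- rep(1, length(w)); total_w <- sum(w[hit]) }
  p_hit <- cumsum(ifelse(hit, w, 0)) / total_w
  p_miss <- cumsum(!hit) / sum(!hit)
  dev <- c(0, p_hit - p_miss)
  dev[which.max(abs(dev))]
}

# Hypergeometric upper tail by exhaustive enumeration of all draws.
oracle_hyper_tail <- function(universe, term_genes, n_draw, min_overlap) {
  draws <- utils::combn(universe, n_draw, simplify = FALSE)
  mean(vapply(draws, function(d)
    length(intersect(d, term_genes)) >= min_overlap, logical(1)))
}

# Classical CCA via base R's QR implementation, used as the independent
# reference for the l = 0 fit.
oracle_cca <- function(X, Y) {
  stats::cancor(scale(X, scale = FALSE), scale(Y, scale = FALSE))
}

p_angles <- function(a, b) ccalink:::principal_angles(a, b)
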