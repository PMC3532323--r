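## Preprocessing: batch-structured expression profiles -> one differential
## response vector per compound.

#' Construct a response matrix
#'
#' Thin container for a compounds x genes differential-response matrix with
#' optional provenance (which batch and instance each row came from).
#'
#' @param values Numeric matrix, rows = compounds (or instances), columns =
#'   genes; dimnames required.
#' @param provenance Optional data.frame with one row per matrix row
#'   (columns such as `compound`, `instance`, `batch`).
#' @return A `response_matrix` object.
#' @export
response_matrix <- function(values, provenance = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_input("`values` must have row and column names")
  if (anyNA(values)) stop_input("response matrix contains missing values")
  if (anyDuplicated(colnames(values)))
    stop_input("gene ids must be unique")
  if (is.null(provenance)) {
    provenance <- data.frame(compound = rownames(values),
                             instance = rownames(values),
                             batch = NA_integer_,
                             stringsAsFactors = FALSE)
  }
  structure(list(values = values, provenance = provenance),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d rows x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Consolidate control replicates into a single robust control profile
#'
#' With three or more controls, the single control with the largest summed
#' Euclidean distance to the other controls is removed as an outlier and the
#' mean of the rest is returned. With one or two controls the plain mean is
#' returned: removal is ill-posed when "the other controls" is a single
#' profile. At most one control is ever removed.
#'
#' @param controls Numeric matrix, one row per control replicate, columns =
#'   genes (a single profile may be given as a vector).
#' @return Named list: `profile` (consolidated control vector) and
#'   `removed` (row index of the dropped control, or `NA`).
#' @export
consolidate_controls <- function(controls) {
  if (is.vector(controls)) controls <- matrix(controls, nrow = 1,
                                              dimnames = list("ctrl1",
                                                              names(controls)))
  if (!is.matrix(controls) || nrow(controls) == 0)
    stop_input("`controls` must contain at least one profile")
  if (anyNA(controls)) stop_input("control profiles contain missing values")
  n <- nrow(controls)
  if (n < 3) {
    return(list(profile = colMeans(controls), removed = NA_integer_))
  }
  d <- as.matrix(stats::dist(controls))
  total <- rowSums(d)
  out <- which.max(total)  # ties: first (deterministic)
  list(profile = colMeans(controls[-out, , drop = FALSE]),
       removed = as.integer(out))
}

#' Differential expression of treatments against the consolidated control
#'
#' Subtracts the batch's consolidated control profile from each treatment
#' profile (both on log2 scale), giving one response vector per instance.
#'
#' @param batch A per-batch record with elements `treatments` (matrix,
#'   instances x genes), `controls` (matrix), and optionally `compound_ids`,
#'   `instance_ids`, `batch_id` (as produced by
#'   [simulate_expression_batches()]).
#' @return Matrix of response vectors (instances x genes).
#' @export
differential_expression <- function(batch) {
  if (is.null(batch$controls) || nrow(batch$controls) == 0)
    stop_input("batch has no control profiles")
  if (is.null(batch$treatments))
    stop_input("batch has no treatment profiles")
  if (!identical(colnames(batch$treatments), colnames(batch$controls)))
    stop_input("treatment and control gene ids differ")
  ctrl <- consolidate_controls(batch$controls)$profile
  sweep(batch$treatments, 2, ctrl, `-`)
}

#' Assemble per-instance responses from an expression batch collection
#'
#' Runs [differential_expression()] over every batch and stacks the results
#' into a [response_matrix()] with provenance.
#'
#' @param collection An `expression_batches` object.
#' @return A `response_matrix` with one row per treatment instance.
#' @export
build_response_matrix <- function(collection) {
  if (!inherits(collection, "expression_batches"))
    stop_input("`collection` must be an expression_batches object")
  rows <- list(); prov <- list()
  for (b in collection$batches) {
    if (nrow(b$treatments) == 0) next
    resp <- differential_expression(b)
    rows[[length(rows) + 1L]] <- resp
    prov[[length(prov) + 1L]] <- data.frame(compound = b$compound_ids,
                                            instance = b$instance_ids,
                                            batch = b$batch_id,
                                            stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  provenance <- do.call(rbind, prov)
  rownames(values) <- provenance$instance
  response_matrix(values, provenance)
}

# Pool all control profiles across batches into one matrix.
pooled_controls <- function(collection) {
  do.call(rbind, lapply(collection$batches, `[[`, "controls"))
}

#' Discard the genes with the highest control variance
#'
#' Removes `ceiling(fraction * n_genes)` genes whose variance across the
#' pooled control profiles is largest: variation in untreated measurements is
#' unrelated to compound response and mostly noise. Ties at the cutoff are
#' broken by gene-id order; the order of the remaining genes is preserved.
#'
#' @param responses A `response_matrix`.
#' @param control_profiles Matrix of pooled control profiles (rows =
#'   controls, columns = same gene universe).
#' @param fraction Fraction of genes to discard, `0 <= fraction < 1`.
#' @return The filtered `response_matrix`.
#' @export
filter_high_variance_genes <- function(responses, control_profiles,
                                       fraction = 0.05) {
  if (!inherits(responses, "response_matrix"))
    stop_input("`responses` must be a response_matrix")
  fraction <- check_number(fraction, "fraction", 0)
  if (fraction >= 1) stop_input("`fraction` must be < 1")
  genes <- colnames(responses$values)
  if (!identical(genes, colnames(control_profiles)))
    stop_input("control profiles and responses have different gene ids")
  n_drop <- ceiling(fraction * length(genes))
  if (n_drop == 0) return(responses)
  v <- apply(control_profiles, 2, stats::var)
  drop_idx <- order_desc_by(v, genes)[seq_len(n_drop)]
  keep <- setdiff(seq_along(genes), drop_idx)
  response_matrix(responses$values[, keep, drop = FALSE],
                  responses$provenance)
}

#' Keep the strongest instance per compound
#'
#' When a compound was profiled several times (cell lines, concentrations),
#' retains the instance whose response vector has the largest Euclidean norm.
#' Exact norm ties are broken by lexicographically smallest instance id.
#'
#' @param responses A `response_matrix` whose provenance maps rows to
#'   compounds.
#' @return A `response_matrix` with exactly one row per distinct compound,
#'   rows renamed to compound ids; provenance records which instance was
#'   kept.
#' @export
select_strongest_instance <- function(responses) {
  if (!inherits(responses, "response_matrix"))
    stop_input("`responses` must be a response_matrix")
  prov <- responses$provenance
  norms <- sqrt(rowSums(responses$values^2))
  keep <- integer(0)
  for (cm in unique(prov$compound)) {
    idx <- which(prov$compound == cm)
    nm <- norms[idx]
    best <- idx[nm == max(nm)]
    if (length(best) > 1)
      best <- best[order(prov$instance[best], method = "radix")][1]
    keep <- c(keep, best[1])
  }
  values <- responses$values[keep, , drop = FALSE]
  prov <- prov[keep, , drop = FALSE]
  rownames(values) <- prov$compound
  response_matrix(values, prov)
}
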