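## File formats: TSV matrices, GMT gene sets, annotation tables, YAML
## configuration. All readers reject malformed input with located errors;
## write -> read round-trips are identity.

#' Read a labelled numeric matrix from TSV
#'
#' First column = row ids, header = column ids, tab-separated, UTF-8.
#' Duplicate ids and non-numeric or empty cells are rejected with the
#' offending location.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop_input("%s: expected row ids plus data columns", path)
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_input("%s: duplicate row id '%s'", path, dup[1])
  cols <- colnames(raw)[-1]
  dupc <- cols[duplicated(cols)]
  if (length(dupc)) stop_input("%s: duplicate column id '%s'", path, dupc[1])
  mat <- matrix(NA_real_, nrow(raw), length(cols),
                dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cell <- raw[[j + 1]]
    bad <- which(is.na(cell) | cell == "")
    if (length(bad))
      stop_input("%s: empty cell at row '%s', column '%s'", path,
                 ids[bad[1]], cols[j])
    num <- suppressWarnings(as.numeric(cell))
    nonnum <- which(is.na(num))
    if (length(nonnum))
      stop_input("%s: non-numeric value '%s' at row '%s', column '%s'",
                 path, cell[nonnum[1]], ids[nonnum[1]], cols[j])
    mat[, j] <- num
  }
  mat
}

#' Write a labelled matrix as TSV
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_header Name of the leading id column.
#' @export
write_matrix_tsv <- function(mat, path, id_header = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Standard dialect: one set per line, tab-separated fields `name`,
#' `description`, then gene ids. Blank lines are skipped; duplicate names
#' and gene-less lines are errors.
#'
#' @param path File path.
#' @param universe Optional gene universe (defaults to the union of all
#'   sets).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_input("%s: no gene sets", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1)
  dup <- names_[duplicated(names_)]
  if (length(dup)) stop_input("%s: duplicate set name '%s'", path, dup[1])
  sets <- lapply(seq_along(parts), function(i) {
    fields <- parts[[i]]
    if (length(fields) < 3)
      stop_input("%s: set '%s' (line %d) has no genes", path, fields[1], i)
    genes <- fields[-(1:2)]
    genes[nzchar(genes)]
  })
  names(sets) <- names_
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  gene_set_collection(sets, universe)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read compound annotations from TSV
#'
#' Columns `compound`, `label` and optionally `kind`.
#'
#' @param path File path.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  annotation_set(df)
}

#' Write compound annotations as TSV
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Default pipeline configuration
#'
#' All numeric parameters default to the pipeline's standard values:
#' control-variance filter fraction 0.05, 20 cross-validation folds, 1000
#' permutations for component significance and target resampling,
#' significance threshold 0.05, top-10 component retention, top-20
#' compounds and top-10 gene sets per subcomponent. Override any entry via
#' `...`.
#'
#' @param ... Named overrides.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "ccalink_run",
    # synthetic-study shape (used when no input paths are given)
    synth = list(n = 60L, p = 12L, q = 16L, k = 2L,
                 correlations = c(0.9, 0.6), noise_sd = 0.1,
                 n_genes = 150L, n_sets = 25L, set_size = c(8L, 15L),
                 batches = 3L, controls_per_batch = 3L,
                 effect_size = 1.5, n_labels = 6L, alignment = 0.9),
    # input paths (all NULL -> synthetic study)
    paths = list(descriptors = NULL, responses = NULL, gene_sets = NULL,
                 annotations = NULL),
    variance_filter_fraction = 0.05,
    gsea = list(n_perm = 50L, exponent = 1),
    cca = list(l1 = 0.1, l2 = 0.01, n_components = NULL,
               scale_x = TRUE, scale_y = FALSE,
               grid = NULL, folds = 20L),
    significance = list(n_perm = 1000L, threshold = 0.05),
    retrieval = list(ks = seq(5L, 100L, by = 5L), enabled = TRUE),
    characterize = list(k_compounds = 20L, k_sets = 10L, n_report = 30L,
                        n_top_de = 10L, prior_df = 10, window = 101L,
                        target_draws = 1000L),
    max_components = 10L
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    else cfg[[nm]] <- overrides[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Entries missing from the file keep their defaults; the result
#' round-trips through [write_pipeline_config()] losslessly.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  user <- yaml::read_yaml(path)
  do.call(default_pipeline_config, user)
}

#' Write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
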