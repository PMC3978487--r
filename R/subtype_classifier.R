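# Generic nearest-centroid single-sample molecular-subtype classification
# with pluggable centroid tables (the ssp2003 / ssp2006 / pam50 roles).
# Centroid tables are data, not code: tests ship synthetic fixture models;
# published tables load through the same TSV schema.

#' Construct a centroid model
#'
#' @param table Numeric matrix, genes in rows (unique rownames), subtypes in
#'   columns (at least two; typical labels: luminal_A, luminal_B, HER2,
#'   normal_like, basal). Column order is the documented tie-break order.
#' @param classifier_name Name of the classifier role (e.g. `"pam50"`).
#' @param correlation_method `"spearman"` (default, rank-based and therefore
#'   invariant to monotone transforms of the sample profile) or `"pearson"`.
#' @return A `centroid_model`.
#' @export
centroid_model <- function(table, classifier_name,
                           correlation_method = c("spearman", "pearson")) {
  correlation_method <- match.arg(correlation_method)
  if (!is.matrix(table) || !is.numeric(table))
    stop("centroid table must be a numeric matrix")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("centroid table needs gene ids as rownames and subtype labels as colnames")
  if (ncol(table) < 2L) stop("centroid model needs at least 2 subtypes")
  if (nrow(table) < 2L) stop("each centroid needs at least 2 genes")
  if (anyDuplicated(rownames(table)))
    stop("duplicate gene in centroid table: ",
         paste(unique(rownames(table)[duplicated(rownames(table))]), collapse = ", "))
  structure(list(classifier_name = as.character(classifier_name),
                 subtypes = colnames(table), table = table,
                 correlation_method = correlation_method),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("centroid_model '", x$classifier_name, "': ", nrow(x$table), " genes x ",
      ncol(x$table), " subtypes (", paste(x$subtypes, collapse = ", "), "); ",
      x$correlation_method, " correlation\n", sep = "")
  invisible(x)
}

#' Load a centroid table from TSV
#'
#' Schema: first column `gene_id`, remaining columns one per subtype label,
#' numeric centroid values.
#'
#' @param path Path to the TSV file.
#' @param classifier_name Name for the model; defaults to the file stem.
#' @param correlation_method See [centroid_model()].
#' @return A `centroid_model`.
#' @export
load_centroids <- function(path, classifier_name = NULL,
                           correlation_method = c("spearman", "pearson")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = MISSING_TOKEN)
  if (ncol(df) < 3L)
    stop("centroid file '", path, "' must have gene_id plus at least 2 subtype columns")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene in '", path, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  tab <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(tab)) stop("non-numeric centroid values in '", path, "'")
  rownames(tab) <- genes
  if (is.null(classifier_name))
    classifier_name <- sub("\\.[^.]*$", "", basename(path))
  centroid_model(tab, classifier_name, correlation_method)
}

#' Classify one sample by nearest centroid
#'
#' Restricts to genes shared by the (non-missing) sample profile and the
#' model; with fewer than `min_genes` shared genes the sample is
#' unclassified. Otherwise the profile is correlated with each centroid and
#' the highest correlation wins; exact ties break by the model's subtype
#' order. A best correlation of zero or less also yields `unclassified` (a
#' profile resembling no centroid should not be forced into a subtype).
#'
#' @param expr Named numeric vector: one sample's expression by gene id.
#' @param model A `centroid_model`.
#' @param min_genes Minimum shared genes to attempt classification.
#' @return A list: `label` (subtype or `"unclassified"`), `correlations`
#'   (named per subtype, NA when unclassifiable), `n_genes_used`.
#' @export
classify_sample <- function(expr, model, min_genes = 10) {
  stopifnot(inherits(model, "centroid_model"))
  shared <- intersect(names(expr)[!is.na(expr)], rownames(model$table))
  if (length(shared) < min_genes)
    return(list(label = "unclassified",
                correlations = stats::setNames(rep(NA_real_, length(model$subtypes)),
                                               model$subtypes),
                n_genes_used = length(shared)))
  x <- expr[shared]
  cors <- vapply(model$subtypes, function(s) {
    suppressWarnings(stats::cor(x, model$table[shared, s],
                                method = model$correlation_method))
  }, numeric(1))
  if (all(is.na(cors)) || max(cors, na.rm = TRUE) <= 0)
    return(list(label = "unclassified", correlations = cors,
                n_genes_used = length(shared)))
  best <- which.max(replace(cors, is.na(cors), -Inf))  # first max = model order
  list(label = model$subtypes[best], correlations = cors,
       n_genes_used = length(shared))
}

#' Classify every sample in a study collection
#'
#' @param collection A `study_collection`.
#' @param model A `centroid_model`.
#' @param min_genes Passed to [classify_sample()].
#' @return Data frame: sample_id, dataset_id, label, best_correlation,
#'   n_genes_used.
#' @export
classify_collection <- function(collection, model, min_genes = 10) {
  stopifnot(inherits(collection, "study_collection"))
  out <- lapply(collection$bundles, function(b) {
    v <- b$gene_matrix$values
    rows <- lapply(colnames(v), function(s) {
      call <- classify_sample(v[, s], model, min_genes = min_genes)
      data.frame(sample_id = s, dataset_id = b$dataset_id, label = call$label,
                 best_correlation = if (all(is.na(call$correlations))) NA_real_
                                    else max(call$correlations, na.rm = TRUE),
                 n_genes_used = call$n_genes_used, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  n_uncl <- sum(out$label == "unclassified")
  if (n_uncl > 0L)
    message(n_uncl, " of ", nrow(out), " samples unclassified by '",
            model$classifier_name, "'")
  out
}
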