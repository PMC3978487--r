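# Intronic miRNAs are frequently embedded in the introns of protein-coding
# host genes, so host-gene expression on conventional arrays serves as a
# proxy for miRNA level. This module maps miRNA ids to host genes (from a
# user-supplied map pinned to a miRBase/Ensembl release) and delegates to
# the marker-query pipeline, tagging results with the proxy caveat: host and
# miRNA are not always co-expressed.

#' Load a miRNA-to-host-gene map
#'
#' TSV schema: columns `mirna_id` and `gene_id`; miRNAs with several host
#' genes appear on multiple rows. Exact duplicate rows are dropped with a
#' warning; blank ids are an error.
#'
#' @param path Path to the TSV file.
#' @param provenance Free-text note recording the map's source versions
#'   (e.g. miRBase/Ensembl releases).
#' @return A `host_gene_map`: named list miRNA id -> character vector of
#'   host gene ids, with the provenance as an attribute.
#' @export
load_host_map <- function(path, provenance = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (!all(c("mirna_id", "gene_id") %in% names(df)))
    stop("host map '", path, "' must have columns mirna_id and gene_id")
  if (nrow(df) == 0L) stop("host map '", path, "' is empty")
  df$mirna_id <- trimws(df$mirna_id); df$gene_id <- trimws(df$gene_id)
  if (any(!nzchar(df$mirna_id)) || any(!nzchar(df$gene_id)) ||
      any(is.na(df$mirna_id)) || any(is.na(df$gene_id)))
    stop("host map '", path, "' contains blank ids")
  if (anyDuplicated(df[, c("mirna_id", "gene_id")])) {
    warning("duplicate (mirna, gene) rows in '", path, "' dropped", call. = FALSE)
    df <- unique(df[, c("mirna_id", "gene_id")])
  }
  map <- split(df$gene_id, df$mirna_id)
  structure(map, class = "host_gene_map", provenance = provenance)
}

#' Write a host-gene map to TSV
#'
#' @param map A `host_gene_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_host_map <- function(map, path) {
  stopifnot(inherits(map, "host_gene_map"))
  df <- data.frame(mirna_id = rep(names(map), lengths(map)),
                   gene_id = unlist(map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve a miRNA to host genes measured in a collection
#'
#' @param mirna_id miRNA identifier present in `map`.
#' @param map A `host_gene_map`.
#' @param collection A `study_collection`.
#' @return Character vector of host gene ids measured in at least one
#'   dataset; warns when some hosts are unmeasured, errors when all are.
#' @export
resolve_mirna <- function(mirna_id, map, collection) {
  stopifnot(inherits(map, "host_gene_map"), inherits(collection, "study_collection"))
  hosts <- map[[mirna_id]]
  if (is.null(hosts)) stop("unknown miRNA '", mirna_id, "'")
  measured <- intersect(hosts, collection$gene_universe)
  if (length(measured) == 0L)
    stop("host gene not measured for '", mirna_id, "': ",
         paste(hosts, collapse = ", "))
  if (length(measured) < length(hosts))
    warning("host gene(s) of '", mirna_id, "' not measured: ",
            paste(setdiff(hosts, measured), collapse = ", "), call. = FALSE)
  measured
}

#' Run a survival query on a miRNA via its host gene(s)
#'
#' Delegates to [run_query()] on the host-gene expression, one result per
#' measured host gene (multi-host miRNAs are never averaged). Each result is
#' tagged with the miRNA id and `proxy = TRUE`, flagging the assumption that
#' host-gene expression tracks the miRNA.
#'
#' @param mirna_id miRNA identifier.
#' @param map A `host_gene_map`.
#' @param collection A `study_collection`.
#' @param ... Query options forwarded to [query_spec()] (all but `gene_ids`).
#' @return List of `marker_result`, one per host gene, each with elements
#'   `mirna_id` and `proxy` added.
#' @export
run_mirna_query <- function(mirna_id, map, collection, ...) {
  hosts <- resolve_mirna(mirna_id, map, collection)
  lapply(hosts, function(g) {
    r <- run_query(collection, query_spec(g, ...))
    r$mirna_id <- mirna_id
    r$proxy <- TRUE
    r
  })
}
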