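# Within-dataset dichotomization into high/low expression groups and
# multi-marker combination. Cut-offs are computed per dataset, never across
# datasets, so pooled results depend only on within-cohort ranks.

CUTOFF_RULES <- c("median", "upper_quartile", "lower_quartile")

.cutoff_value <- function(values, rule) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L)
    stop("degenerate distribution: fewer than 2 non-missing values")
  p <- switch(rule, median = 0.5, upper_quartile = 0.75, lower_quartile = 0.25)
  # linear-interpolation quantile of the non-missing values
  unname(stats::quantile(obs, probs = p, type = 7, names = FALSE))
}

.apply_cutoff <- function(values, cutoff, rule) {
  lab <- rep("excluded", length(values))
  obs <- !is.na(values)
  lab[obs] <- switch(rule,
    median         = ifelse(values[obs] > cutoff, "high", "low"),
    upper_quartile = ifelse(values[obs] > cutoff, "high", "low"),
    lower_quartile = ifelse(values[obs] < cutoff, "low", "high"))
  names(lab) <- names(values)
  lab
}

#' Dichotomize one gene's expression within a cohort
#'
#' Splits samples at a within-cohort cut-off: `median` labels a sample high
#' iff its value is strictly greater than the median (ties go low);
#' `upper_quartile` labels high iff strictly above the 75th percentile;
#' `lower_quartile` labels low iff strictly below the 25th percentile (ties go
#' high). Percentiles are linear-interpolation quantiles of the non-missing
#' values; missing values are labelled `excluded`.
#'
#' @param values Named numeric vector of expression for one gene, one cohort.
#' @param rule One of `"median"`, `"upper_quartile"`, `"lower_quartile"`.
#' @return Character vector of labels in `{high, low, excluded}`, named as
#'   `values`.
#' @export
dichotomize <- function(values, rule = c("median", "upper_quartile", "lower_quartile")) {
  rule <- match.arg(rule)
  .apply_cutoff(values, .cutoff_value(values, rule), rule)
}

.group_assignment <- function(dataset_id, gene_ids, rule, labels) {
  stopifnot(all(labels %in% c("high", "low", "excluded")), !is.null(names(labels)))
  structure(list(dataset_id = dataset_id, gene_ids = gene_ids, rule = rule,
                 labels = labels),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("high", "low", "excluded")))
  cat("group_assignment '", x$dataset_id, "' [", paste(x$gene_ids, collapse = "+"),
      ", ", x$rule, "]: ", tab[["high"]], " high / ", tab[["low"]], " low / ",
      tab[["excluded"]], " excluded\n", sep = "")
  invisible(x)
}

#' Combine marker assignments within a dataset
#'
#' `all_high` labels a sample high only when every input assignment labels it
#' high (e.g. above-median for both markers); otherwise low. `all_low` is the
#' symmetric rule on low. A sample excluded by any input is excluded.
#'
#' @param assignments List of two or more `group_assignment` objects sharing
#'   dataset id and sample order.
#' @param rule `"all_high"` or `"all_low"`.
#' @return A combined `group_assignment` over the union of the gene ids.
#' @export
combine_markers <- function(assignments, rule = c("all_high", "all_low")) {
  rule <- match.arg(rule)
  stopifnot(length(assignments) >= 2L,
            all(vapply(assignments, inherits, logical(1), "group_assignment")))
  ids <- unique(vapply(assignments, `[[`, character(1), "dataset_id"))
  if (length(ids) != 1L) stop("assignments come from different datasets")
  samples <- names(assignments[[1]]$labels)
  for (a in assignments[-1])
    if (!identical(names(a$labels), samples))
      stop("assignments have mismatched sample sets")
  mat <- vapply(assignments, `[[`, character(length(samples)), "labels")
  target <- if (rule == "all_high") "high" else "low"
  other <- if (rule == "all_high") "low" else "high"
  lab <- apply(mat, 1L, function(r) {
    if (any(r == "excluded")) "excluded"
    else if (all(r == target)) target
    else other
  })
  names(lab) <- samples
  .group_assignment(ids, unlist(lapply(assignments, `[[`, "gene_ids")),
                    assignments[[1]]$rule, lab)
}

#' Assign high/low groups across a study collection
#'
#' Per dataset: samples failing the clinical filter (and, when given, the
#' subtype restriction) are excluded; cut-offs are computed within the
#' filtered sub-cohort (`cutoff_scope = "filtered"`, the default) or over all
#' samples (`"full"`); datasets missing any queried gene contribute no
#' assignment and are reported with a warning. Multi-gene queries are
#' combined per [combine_markers()].
#'
#' @param collection A `study_collection`.
#' @param gene_ids One or more gene ids; `combine = "single"` requires one.
#' @param rule Cut-off rule; see [dichotomize()].
#' @param combine `"single"`, `"all_high"` or `"all_low"`.
#' @param filter A [filter_spec()]; the empty filter keeps all samples.
#' @param include_samples Optional named list (dataset id -> sample ids)
#'   restricting each cohort, e.g. to one molecular subtype.
#' @param cutoff_scope `"filtered"` or `"full"`.
#' @return List of `group_assignment`, one per contributing dataset.
#' @export
assign_groups <- function(collection, gene_ids,
                          rule = c("median", "upper_quartile", "lower_quartile"),
                          combine = c("single", "all_high", "all_low"),
                          filter = filter_spec(),
                          include_samples = NULL,
                          cutoff_scope = c("filtered", "full")) {
  rule <- match.arg(rule); combine <- match.arg(combine)
  cutoff_scope <- match.arg(cutoff_scope)
  stopifnot(inherits(collection, "study_collection"), length(gene_ids) >= 1L)
  if (combine == "single" && length(gene_ids) != 1L)
    stop("combine = 'single' requires exactly one gene id")
  out <- list()
  for (b in collection$bundles) {
    v <- b$gene_matrix$values
    if (!all(gene_ids %in% rownames(v))) {
      warning("dataset '", b$dataset_id, "' lacks gene(s) ",
              paste(setdiff(gene_ids, rownames(v)), collapse = ", "),
              "; skipped", call. = FALSE)
      next
    }
    keep <- apply_filter(b, filter)
    if (!is.null(include_samples))
      keep <- intersect(keep, include_samples[[b$dataset_id]])
    if (length(keep) == 0L) next
    per_gene <- vector("list", length(gene_ids))
    ok <- TRUE
    for (k in seq_along(gene_ids)) {
      x <- v[gene_ids[k], , drop = TRUE]
      scope <- if (cutoff_scope == "filtered") x[keep] else x
      if (sum(!is.na(scope)) < 2L) { ok <- FALSE; break }
      cut <- .cutoff_value(scope, rule)
      lab <- rep("excluded", ncol(v)); names(lab) <- colnames(v)
      lab[keep] <- .apply_cutoff(x[keep], cut, rule)
      per_gene[[k]] <- .group_assignment(b$dataset_id, gene_ids[k], rule, lab)
    }
    if (!ok) {
      warning("dataset '", b$dataset_id,
              "' has a degenerate expression distribution after filtering; skipped",
              call. = FALSE)
      next
    }
    out[[b$dataset_id]] <- if (length(per_gene) == 1L) per_gene[[1]]
      else combine_markers(per_gene, combine)
  }
  if (length(out) == 0L)
    stop("gene not measured: no dataset carries all of ",
         paste(gene_ids, collapse = ", "))
  out
}

#' Export group assignments as a data frame
#'
#' @param assignments List of `group_assignment`.
#' @return Data frame with columns sample_id, dataset_id, label, suitable for
#'   TSV audit export.
#' @export
assignments_table <- function(assignments) {
  do.call(rbind, lapply(assignments, function(a) {
    data.frame(sample_id = names(a$labels), dataset_id = a$dataset_id,
               label = unname(a$labels), stringsAsFactors = FALSE)
  }))
}
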