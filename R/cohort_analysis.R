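# Query orchestration: clinical filtering, subtype stratification, the
# end-to-end marker query, and endpoint x cut-off x classifier sweeps with
# the consensus significance rule.

#' Specify a clinical filter
#'
#' Each stated constraint must be satisfied for a sample to pass; a sample
#' with a missing value in any constrained field is excluded; unconstrained
#' fields never exclude anyone. The empty filter keeps every sample.
#'
#' @param er_status,pr_status,her2_status,ln_status `"pos"` or `"neg"`.
#' @param grade Subset of `c(1, 2, 3)`.
#' @param chemo,hormone `"yes"` or `"no"`.
#' @param age Closed interval in years, `c(min, max)`.
#' @param size Closed interval in cm, `c(min, max)`.
#' @return A `filter_spec`.
#' @export
filter_spec <- function(er_status = NULL, pr_status = NULL, her2_status = NULL,
                        ln_status = NULL, grade = NULL, chemo = NULL,
                        hormone = NULL, age = NULL, size = NULL) {
  chk_enum <- function(x, allowed, nm) {
    if (!is.null(x) && (length(x) != 1L || !x %in% allowed))
      stop(nm, " constraint must be one of ", paste(allowed, collapse = "/"))
    x
  }
  chk_interval <- function(x, nm) {
    if (!is.null(x)) {
      if (length(x) != 2L || any(is.na(x)) || x[1] > x[2])
        stop(nm, " must be a well-ordered interval c(min, max)")
      x <- as.numeric(x)
    }
    x
  }
  if (!is.null(grade) && !all(grade %in% 1:3))
    stop("grade constraint must be a subset of 1:3")
  structure(list(
    er_status = chk_enum(er_status, c("pos", "neg"), "er_status"),
    pr_status = chk_enum(pr_status, c("pos", "neg"), "pr_status"),
    her2_status = chk_enum(her2_status, c("pos", "neg"), "her2_status"),
    ln_status = chk_enum(ln_status, c("pos", "neg"), "ln_status"),
    grade = if (is.null(grade)) NULL else as.integer(grade),
    chemo = chk_enum(chemo, c("yes", "no"), "chemo"),
    hormone = chk_enum(hormone, c("yes", "no"), "hormone"),
    age = chk_interval(age, "age"), size = chk_interval(size, "size")),
    class = "filter_spec")
}

#' Apply a clinical filter to a dataset
#'
#' @param b A `dataset_bundle`.
#' @param f A [filter_spec()].
#' @return Character vector of sample ids passing every constraint.
#' @export
apply_filter <- function(b, f) {
  stopifnot(inherits(b, "dataset_bundle"), inherits(f, "filter_spec"))
  cl <- b$clinical
  pass <- rep(TRUE, nrow(cl))
  for (nm in c("er_status", "pr_status", "her2_status", "ln_status", "chemo", "hormone"))
    if (!is.null(f[[nm]]))
      pass <- pass & !is.na(cl[[nm]]) & cl[[nm]] == f[[nm]]
  if (!is.null(f$grade))
    pass <- pass & !is.na(cl$grade) & cl$grade %in% f$grade
  if (!is.null(f$age))
    pass <- pass & !is.na(cl$age) & cl$age >= f$age[1] & cl$age <= f$age[2]
  if (!is.null(f$size))
    pass <- pass & !is.na(cl$size_cm) & cl$size_cm >= f$size[1] & cl$size_cm <= f$size[2]
  cl$sample_id[pass]
}

#' Specify a marker query
#'
#' @param gene_ids One or more gene ids (one unless combining).
#' @param combine `"single"`, `"all_high"` or `"all_low"`.
#' @param cutoff Cut-off rule; see [dichotomize()].
#' @param endpoint `"DFS"`, `"DDFS"` or `"OS"`.
#' @param filter A [filter_spec()].
#' @param subtype Optional molecular subtype to restrict to (a label of the
#'   classifier's centroid model, e.g. `"basal"`); requires `classifier`.
#' @param classifier Optional `centroid_model` used to call subtypes.
#' @param cutoff_scope `"filtered"` or `"full"`; see [assign_groups()].
#' @param stratify_by_dataset Passed to [cox_hr()].
#' @return A `query_spec`.
#' @export
query_spec <- function(gene_ids, combine = c("single", "all_high", "all_low"),
                       cutoff = c("median", "upper_quartile", "lower_quartile"),
                       endpoint = c("DFS", "DDFS", "OS"),
                       filter = filter_spec(), subtype = NULL, classifier = NULL,
                       cutoff_scope = c("filtered", "full"),
                       stratify_by_dataset = FALSE) {
  combine <- match.arg(combine); cutoff <- match.arg(cutoff)
  endpoint <- match.arg(endpoint); cutoff_scope <- match.arg(cutoff_scope)
  stopifnot(length(gene_ids) >= 1L, inherits(filter, "filter_spec"))
  if (combine == "single" && length(gene_ids) != 1L)
    stop("combine = 'single' requires exactly one gene id")
  if (!is.null(subtype) && is.null(classifier))
    stop("a subtype restriction requires a classifier")
  if (!is.null(classifier)) stopifnot(inherits(classifier, "centroid_model"))
  structure(list(gene_ids = as.character(gene_ids), combine = combine,
                 cutoff = cutoff, endpoint = endpoint, filter = filter,
                 subtype = subtype, classifier = classifier,
                 cutoff_scope = cutoff_scope,
                 stratify_by_dataset = stratify_by_dataset),
            class = "query_spec")
}

#' Run one end-to-end marker query
#'
#' Pipeline: optional subtype calls on the full collection, then per-dataset
#' clinical filtering, per-dataset dichotomization (and marker combination),
#' pooling of group labels across datasets, and Kaplan-Meier / log-rank /
#' Cox analysis of the pooled two-group cohort.
#'
#' @param collection A `study_collection`.
#' @param q A [query_spec()].
#' @return A `marker_result`: the [analyze_pooled()] output plus the query,
#'   per-dataset n, and any warnings raised along the way.
#' @export
run_query <- function(collection, q) {
  stopifnot(inherits(collection, "study_collection"), inherits(q, "query_spec"))
  missing_genes <- setdiff(q$gene_ids, collection$gene_universe)
  if (length(missing_genes) > 0L)
    stop("gene not measured: ", paste(missing_genes, collapse = ", "))
  warnings <- character(0)
  include <- NULL
  if (!is.null(q$subtype)) {
    calls <- classify_collection(collection, q$classifier)
    include <- split(calls$sample_id[calls$label %in% q$subtype],
                     calls$dataset_id[calls$label %in% q$subtype])
  }
  res <- withCallingHandlers({
    assignments <- assign_groups(collection, q$gene_ids, rule = q$cutoff,
                                 combine = q$combine, filter = q$filter,
                                 include_samples = include,
                                 cutoff_scope = q$cutoff_scope)
    analyze_pooled(assignments, collection, endpoint = q$endpoint,
                   stratify_by_dataset = q$stratify_by_dataset)
  }, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  structure(c(res, list(query = q, warnings = warnings)),
            class = "marker_result")
}

#' @export
print.marker_result <- function(x, ...) {
  cat("Marker query: ", paste(x$query$gene_ids, collapse = "+"),
      " | ", x$query$endpoint, " | ", x$query$cutoff,
      if (!is.null(x$query$subtype)) paste0(" | subtype ", x$query$subtype) else "",
      "\n", sep = "")
  print(x$result)
  cat("datasets: ", paste(sprintf("%s (%d)", names(x$per_dataset_n), x$per_dataset_n),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Flatten marker results to a one-row data frame
#'
#' @param x A `marker_result`.
#' @return One-row data frame with query descriptors and statistics;
#'   per-dataset n packed as `"id=n;id=n"`.
#' @export
result_row <- function(x) {
  stopifnot(inherits(x, "marker_result"))
  r <- x$result
  data.frame(
    genes = paste(x$query$gene_ids, collapse = "+"),
    endpoint = x$query$endpoint, cutoff = x$query$cutoff,
    combine = x$query$combine,
    subtype = if (is.null(x$query$subtype)) NA_character_ else x$query$subtype,
    n = r$n, events = r$events, hr = r$hr, ci_low = r$ci_low,
    ci_high = r$ci_high, logrank_chi2 = r$logrank_chi2, logrank_p = r$logrank_p,
    separation = r$separation,
    per_dataset_n = paste(sprintf("%s=%d", names(x$per_dataset_n), x$per_dataset_n),
                          collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Consensus significance rule
#'
#' A marker is called significant when its p-value is strictly below `alpha`
#' under at least `min_classifiers` of the attempted classifiers (default:
#' two of three at 0.05). NA cells count as attempted but never as
#' significant.
#'
#' @param p P-values, one per classifier cell (NA allowed).
#' @param alpha Significance threshold (strict inequality).
#' @param min_classifiers Number of classifiers required below `alpha`.
#' @return Logical flag.
#' @export
consensus_significant <- function(p, alpha = 0.05, min_classifiers = 2) {
  sum(p < alpha, na.rm = TRUE) >= min_classifiers
}

#' Sweep markers over endpoints, cut-offs and subtype classifiers
#'
#' Runs one query per (gene, endpoint, cutoff, classifier) cell within one
#' molecular subtype, then applies the consensus rule per (gene, endpoint,
#' cutoff): the call is significant when the log-rank p-value is strictly
#' below `alpha` under at least `min_classifiers` classifiers. Cells that
#' fail (e.g. an endpoint absent from every cohort) are recorded as NA and
#' still count as attempted classifiers.
#'
#' @param collection A `study_collection`.
#' @param genes Character vector of gene ids.
#' @param endpoints Subset of `c("DFS", "DDFS", "OS")`.
#' @param cutoffs Subset of the cut-off rules.
#' @param classifiers Named list of `centroid_model` objects; may be a single
#'   unnamed model. Use `NULL` for an unstratified sweep (one cell per
#'   combination, consensus over that single cell).
#' @param filter A [filter_spec()] applied in every cell.
#' @param subtype Subtype restriction (required when classifiers are given).
#' @param alpha Significance threshold (strict inequality).
#' @param min_classifiers Consensus count required.
#' @param adjust Apply Benjamini-Hochberg adjustment across all cells' p
#'   values before the consensus rule; off by default.
#' @return List with `cells` (one row per query cell) and `calls` (one
#'   consensus row per gene x endpoint x cutoff).
#' @export
sweep_markers <- function(collection, genes, endpoints = "DFS",
                          cutoffs = "median", classifiers = NULL,
                          filter = filter_spec(), subtype = NULL,
                          alpha = 0.05, min_classifiers = 2, adjust = FALSE) {
  stopifnot(length(genes) >= 1L, length(endpoints) >= 1L, length(cutoffs) >= 1L)
  if (is.null(classifiers)) {
    classifiers <- list(none = NULL)
  } else {
    if (inherits(classifiers, "centroid_model")) classifiers <- list(classifiers)
    if (is.null(names(classifiers)))
      names(classifiers) <- vapply(classifiers, `[[`, character(1), "classifier_name")
  }
  cells <- list()
  for (g in genes) for (ep in endpoints) for (co in cutoffs)
    for (clf in names(classifiers)) {
      cell <- tryCatch({
        q <- query_spec(g, cutoff = co, endpoint = ep, filter = filter,
                        subtype = subtype, classifier = classifiers[[clf]])
        r <- run_query(collection, q)$result
        data.frame(gene = g, endpoint = ep, cutoff = co, classifier = clf,
                   hr = r$hr, p = r$logrank_p, n = r$n, error = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(gene = g, endpoint = ep, cutoff = co, classifier = clf,
                   hr = NA_real_, p = NA_real_, n = NA_integer_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      cells[[length(cells) + 1L]] <- cell
    }
  cells <- do.call(rbind, cells)
  p_used <- if (adjust) adjust_bh(cells$p) else cells$p
  cells$p_adj <- if (adjust) p_used else NA_real_
  key <- interaction(cells$gene, cells$endpoint, cells$cutoff, drop = TRUE)
  calls <- do.call(rbind, lapply(split(seq_len(nrow(cells)), key), function(i) {
    sig_n <- sum(p_used[i] < alpha, na.rm = TRUE)
    data.frame(gene = cells$gene[i][1], endpoint = cells$endpoint[i][1],
               cutoff = cells$cutoff[i][1], n_classifiers = length(i),
               n_significant = sig_n,
               significant = consensus_significant(p_used[i], alpha, min_classifiers),
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  list(cells = cells, calls = calls)
}
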