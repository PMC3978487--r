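# Data containers, TSV readers/writers, probe-to-gene centering and
# dataset-level validation.

MISSING_TOKEN <- "NA"

#' Construct a probe-level expression matrix
#'
#' A `probe_matrix` holds log-scale normalized expression values for one
#' cohort, probes in rows and samples in columns. Missing values are allowed.
#'
#' @param values Numeric matrix, probes x samples, with unique rownames
#'   (probe ids) and unique colnames (sample ids).
#' @param dataset_id Cohort identifier.
#' @return An object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, dataset_id) {
  .check_expr_matrix(values, "probe")
  structure(list(dataset_id = as.character(dataset_id), values = values),
            class = "probe_matrix")
}

#' Construct a gene-level expression matrix
#'
#' @param values Numeric matrix, genes x samples, unique rownames (gene ids)
#'   and colnames (sample ids). No gene row may be entirely missing.
#' @param dataset_id Cohort identifier.
#' @return An object of class `gene_matrix`.
#' @export
gene_matrix <- function(values, dataset_id) {
  .check_expr_matrix(values, "gene")
  all_na <- rowSums(!is.na(values)) == 0L
  if (any(all_na))
    stop("gene rows entirely missing: ", paste(rownames(values)[all_na], collapse = ", "))
  structure(list(dataset_id = as.character(dataset_id), values = values),
            class = "gene_matrix")
}

.check_expr_matrix <- function(values, what) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs ", what, " ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate ", what, " id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix '", x$dataset_id, "': ", nrow(x$values), " probes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat("gene_matrix '", x$dataset_id, "': ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row whose first field is `probe_id` (or `gene_id`),
#' followed by sample ids; one row per probe; numeric cells with `NA` as the
#' missing token. Duplicate probe rows are an error, as is an empty file.
#'
#' @param path Path to the TSV file.
#' @param dataset_id Cohort identifier attached to the result.
#' @param as Return a `"probe"` or `"gene"` level matrix; defaults to the
#'   level announced by the header's first field.
#' @return A [probe_matrix()] or [gene_matrix()].
#' @export
read_expression_matrix <- function(path, dataset_id, as = c("auto", "probe", "gene")) {
  as <- match.arg(as)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("no probes in '", path, "': empty file")
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 2L)
    stop("malformed header in '", path, "': expected probe_id column plus sample ids")
  level <- if (as == "auto") {
    if (identical(fields[1], "gene_id")) "gene" else "probe"
  } else as
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = MISSING_TOKEN)
  if (nrow(df) == 0L) stop("no probes in '", path, "'")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate probe id in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell in '", path, "' at row '", ids[bad[1, 1]],
         "', column '", colnames(raw)[bad[1, 2]], "': '", raw[bad[1, , drop = FALSE]], "'")
  dimnames(num) <- list(ids, colnames(raw))
  if (level == "gene") gene_matrix(num, dataset_id) else probe_matrix(num, dataset_id)
}

#' Write a gene-level expression matrix to TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param gm A [gene_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_matrix <- function(gm, path) {
  stopifnot(inherits(gm, "gene_matrix"))
  v <- gm$values
  fmt <- ifelse(is.na(v), MISSING_TOKEN, sprintf("%.17g", v))
  dim(fmt) <- dim(v)
  lines <- c(paste(c("gene_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)),
                    function(i) paste(c(rownames(v)[i], fmt[i, ]), collapse = "\t"),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' TSV with columns `probe_id` and `gene_id`; probes hitting multiple genes
#' appear on multiple rows.
#'
#' @param path Path to the TSV file.
#' @return A `probe_annotation`: data frame with columns probe_id, gene_id.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    stop("annotation file '", path, "' must have columns probe_id and gene_id")
  probe_annotation(df$probe_id, df$gene_id)
}

#' Construct a probe annotation from parallel vectors
#'
#' @param probe_id,gene_id Character vectors of equal length; one row per
#'   (probe, gene) pair.
#' @return A `probe_annotation` data frame.
#' @export
probe_annotation <- function(probe_id, gene_id) {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  stopifnot(length(probe_id) == length(gene_id))
  if (any(!nzchar(gene_id)) || any(is.na(gene_id)))
    stop("annotation contains blank gene ids")
  df <- unique(data.frame(probe_id = probe_id, gene_id = gene_id,
                          stringsAsFactors = FALSE))
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Collapse probes to genes
#'
#' Probes mapping to more than one gene are discarded; probes absent from the
#' annotation are dropped; each gene's row is the arithmetic mean (on the
#' stored log scale) of its surviving probes, computed per sample over
#' non-missing values.
#'
#' @param pm A [probe_matrix()].
#' @param ann A `probe_annotation` sharing `pm`'s probe namespace.
#' @return A [gene_matrix()] whose rows are the mappable genes.
#' @export
gene_center <- function(pm, ann) {
  stopifnot(inherits(pm, "probe_matrix"), inherits(ann, "probe_annotation"))
  n_genes <- table(ann$probe_id)
  multi <- names(n_genes)[n_genes > 1L]
  ann1 <- ann[!(ann$probe_id %in% multi), , drop = FALSE]
  keep <- intersect(rownames(pm$values), ann1$probe_id)
  if (length(keep) == 0L) stop("no mappable probes for dataset '", pm$dataset_id, "'")
  map <- ann1$gene_id[match(keep, ann1$probe_id)]
  v <- pm$values[keep, , drop = FALSE]
  genes <- unique(map)
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  for (g in genes) {
    rows <- v[map == g, , drop = FALSE]
    out[g, ] <- colMeans(rows, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out <- out[rowSums(!is.na(out)) > 0L, , drop = FALSE]
  if (nrow(out) == 0L) stop("no mappable probes for dataset '", pm$dataset_id, "'")
  gene_matrix(out, pm$dataset_id)
}

## ---- clinical tables --------------------------------------------------

ENDPOINTS <- c("DFS", "DDFS", "OS")

CLINICAL_COLUMNS <- c("sample_id", "age", "size_cm", "ln_status", "er_status",
                      "pr_status", "her2_status", "grade", "chemo", "hormone",
                      "dfs_time", "dfs_event", "ddfs_time", "ddfs_event",
                      "os_time", "os_event")

# fixed synonym tables for categorical clinical fields
.POS_NEG <- c(pos = "pos", positive = "pos", "p" = "pos", "1" = "pos", "+" = "pos",
              neg = "neg", negative = "neg", "n" = "neg", "0" = "neg", "-" = "neg")
.YES_NO <- c(yes = "yes", y = "yes", "1" = "yes", "true" = "yes", treated = "yes",
             no = "no", "n" = "no", "0" = "no", "false" = "no", untreated = "no")

.normalize_enum <- function(x, table, field) {
  x <- tolower(trimws(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  out <- unname(table[x])
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown))
    warning("unrecognized ", field, " value(s) set to missing: ",
            paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
  out
}

#' Construct a clinical table
#'
#' Normalizes clinical covariates and survival endpoints for one cohort.
#' Recognized columns: `sample_id` (required), `age` (years), `size_cm` (cm),
#' `ln_status`, `er_status`, `pr_status`, `her2_status` (pos/neg), `grade`
#' (1-3), `chemo`, `hormone` (yes/no), and per endpoint `dfs_time`/`dfs_event`,
#' `ddfs_time`/`ddfs_event`, `os_time`/`os_event` (months, 0/1). Missing
#' columns are filled with missing values; unknown columns are ignored.
#' An endpoint time without its event flag (or vice versa) is coerced to
#' missing with a warning, as is an out-of-range grade or a negative time.
#'
#' @param df Data frame with at least a `sample_id` column.
#' @return A `clinical_table` data frame with all recognized columns.
#' @export
clinical_table <- function(df) {
  if (!"sample_id" %in% names(df)) stop("clinical table lacks a sample_id column")
  n <- nrow(df)
  out <- data.frame(sample_id = as.character(df$sample_id), stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample id in clinical table: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  num_col <- function(nm) if (nm %in% names(df)) suppressWarnings(as.numeric(df[[nm]])) else rep(NA_real_, n)
  out$age <- num_col("age")
  out$size_cm <- num_col("size_cm")
  for (nm in c("ln_status", "er_status", "pr_status", "her2_status"))
    out[[nm]] <- if (nm %in% names(df)) .normalize_enum(df[[nm]], .POS_NEG, nm) else rep(NA_character_, n)
  grade <- num_col("grade")
  bad <- !is.na(grade) & !(grade %in% 1:3)
  if (any(bad))
    warning("grade outside 1-3 set to missing for ", sum(bad), " sample(s)", call. = FALSE)
  grade[bad] <- NA_real_
  out$grade <- as.integer(grade)
  for (nm in c("chemo", "hormone"))
    out[[nm]] <- if (nm %in% names(df)) .normalize_enum(df[[nm]], .YES_NO, nm) else rep(NA_character_, n)
  for (ep in tolower(ENDPOINTS)) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    tm <- num_col(tcol); ev <- num_col(ecol)
    neg <- !is.na(tm) & tm < 0
    if (any(neg)) {
      warning("negative ", tcol, " set to missing for ", sum(neg), " sample(s)", call. = FALSE)
      tm[neg] <- NA_real_
    }
    bad_ev <- !is.na(ev) & !(ev %in% c(0, 1))
    if (any(bad_ev)) {
      warning(ecol, " outside {0,1} set to missing for ", sum(bad_ev), " sample(s)", call. = FALSE)
      ev[bad_ev] <- NA_real_
    }
    half <- xor(is.na(tm), is.na(ev))
    if (any(half)) {
      warning("incomplete ", toupper(ep), " endpoint (time xor event) set to missing for ",
              sum(half), " sample(s)", call. = FALSE)
      tm[half] <- NA_real_; ev[half] <- NA_real_
    }
    out[[tcol]] <- tm
    out[[ecol]] <- as.integer(ev)
  }
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Read a clinical table from TSV
#'
#' @param path Path to a tab-separated file with a `sample_id` column; see
#'   [clinical_table()] for recognized columns and normalization rules.
#' @return A `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = MISSING_TOKEN)
  clinical_table(df)
}

#' Write a clinical table to TSV
#'
#' @param ct A `clinical_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(ct, path) {
  stopifnot(inherits(ct, "clinical_table"))
  out <- ct
  for (nm in c("age", "size_cm", "dfs_time", "ddfs_time", "os_time"))
    out[[nm]] <- ifelse(is.na(ct[[nm]]), MISSING_TOKEN, sprintf("%.17g", ct[[nm]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = MISSING_TOKEN)
  invisible(path)
}

#' Which endpoints does a clinical table carry?
#'
#' @param ct A `clinical_table`.
#' @return Subset of `c("DFS", "DDFS", "OS")` with at least one complete
#'   (time, event) pair.
#' @export
endpoints_present <- function(ct) {
  present <- vapply(tolower(ENDPOINTS), function(ep) {
    any(!is.na(ct[[paste0(ep, "_time")]]) & !is.na(ct[[paste0(ep, "_event")]]))
  }, logical(1))
  ENDPOINTS[present]
}

## ---- bundles and collections ------------------------------------------

#' Bundle a gene matrix with its clinical table
#'
#' @param gm A [gene_matrix()].
#' @param clinical A `clinical_table` covering exactly `gm`'s samples, in the
#'   same order (reordered automatically when the sets match).
#' @return A `dataset_bundle`.
#' @export
dataset_bundle <- function(gm, clinical) {
  stopifnot(inherits(gm, "gene_matrix"), inherits(clinical, "clinical_table"))
  sm <- colnames(gm$values)
  if (!setequal(sm, clinical$sample_id))
    stop("expression and clinical sample sets differ for dataset '", gm$dataset_id, "'")
  clinical <- clinical[match(sm, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  class(clinical) <- c("clinical_table", "data.frame")
  structure(list(dataset_id = gm$dataset_id, gene_matrix = gm, clinical = clinical),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("dataset_bundle '", x$dataset_id, "': ", nrow(x$gene_matrix$values),
      " genes x ", ncol(x$gene_matrix$values), " samples; endpoints: ",
      paste(endpoints_present(x$clinical), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a dataset against the inclusion rule
#'
#' A cohort is included when it has survival information for at least one
#' endpoint and at least `min_samples` patients (48 by default, a curation
#' policy mirroring the smallest usable public breast cancer cohorts).
#'
#' @param b A `dataset_bundle`.
#' @param min_samples Minimum cohort size.
#' @return A `validation_report` list: `dataset_id`, `n_samples`,
#'   `endpoints_present`, `passes_inclusion`, `messages`.
#' @export
validate_dataset <- function(b, min_samples = 48) {
  stopifnot(inherits(b, "dataset_bundle"))
  n <- ncol(b$gene_matrix$values)
  eps <- endpoints_present(b$clinical)
  msgs <- character(0)
  if (n < min_samples)
    msgs <- c(msgs, sprintf("only %d samples (< %d required)", n, min_samples))
  if (length(eps) == 0L)
    msgs <- c(msgs, "no survival information")
  structure(list(dataset_id = b$dataset_id, n_samples = n,
                 endpoints_present = eps,
                 passes_inclusion = n >= min_samples && length(eps) > 0L,
                 messages = msgs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("dataset '", x$dataset_id, "': n=", x$n_samples, ", endpoints [",
      paste(x$endpoints_present, collapse = ", "), "] -> ",
      if (x$passes_inclusion) "included" else "excluded", "\n", sep = "")
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Assemble a study collection from dataset bundles
#'
#' @param bundles List of `dataset_bundle` objects with distinct dataset ids.
#' @param enforce_inclusion Drop bundles failing [validate_dataset()] (with a
#'   warning) before assembly.
#' @param min_samples Passed to [validate_dataset()] when enforcing.
#' @return A `study_collection`: `bundles` (named by dataset id) and
#'   `gene_universe` (the exact union of gene ids).
#' @export
build_collection <- function(bundles, enforce_inclusion = FALSE, min_samples = 48) {
  stopifnot(length(bundles) >= 1L,
            all(vapply(bundles, inherits, logical(1), "dataset_bundle")))
  ids <- vapply(bundles, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids))
    stop("duplicate dataset id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (enforce_inclusion) {
    ok <- vapply(bundles, function(b) validate_dataset(b, min_samples)$passes_inclusion,
                 logical(1))
    if (any(!ok))
      warning("excluded dataset(s): ", paste(ids[!ok], collapse = ", "), call. = FALSE)
    bundles <- bundles[ok]; ids <- ids[ok]
    if (length(bundles) == 0L) stop("all datasets excluded by the inclusion rule")
  }
  names(bundles) <- ids
  universe <- sort(unique(unlist(lapply(bundles, function(b) rownames(b$gene_matrix$values)))))
  structure(list(bundles = bundles, gene_universe = universe),
            class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  ns <- vapply(x$bundles, function(b) ncol(b$gene_matrix$values), integer(1))
  cat("study_collection: ", length(x$bundles), " datasets, ", sum(ns),
      " samples, ", length(x$gene_universe), " genes in universe\n", sep = "")
  invisible(x)
}

#' Read a study collection from a dataset manifest
#'
#' The manifest (JSON or YAML) lists one record per dataset with fields `id`,
#' `expression`, `clinical` and optionally `annotation`; paths are resolved
#' relative to the manifest. With an annotation the expression file is read at
#' probe level and collapsed through [gene_center()]; without one it must
#' already be gene-centered.
#'
#' @param manifest_path Path to a JSON (`.json`) or YAML manifest with a
#'   top-level `datasets` list.
#' @param enforce_inclusion,min_samples Passed to [build_collection()].
#' @return A `study_collection`.
#' @export
read_collection <- function(manifest_path, enforce_inclusion = FALSE, min_samples = 48) {
  man <- if (grepl("\\.json$", manifest_path, ignore.case = TRUE)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(manifest_path)
  }
  if (is.null(man$datasets) || length(man$datasets) == 0L)
    stop("manifest '", manifest_path, "' lists no datasets")
  base <- dirname(manifest_path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  bundles <- lapply(man$datasets, function(d) {
    if (is.null(d$id) || is.null(d$expression) || is.null(d$clinical))
      stop("manifest entry needs id, expression and clinical fields")
    clin <- read_clinical_table(resolve(d$clinical))
    gm <- if (!is.null(d$annotation)) {
      pm <- read_expression_matrix(resolve(d$expression), d$id, as = "probe")
      gene_center(pm, read_probe_annotation(resolve(d$annotation)))
    } else {
      read_expression_matrix(resolve(d$expression), d$id, as = "gene")
    }
    dataset_bundle(gm, clin)
  })
  build_collection(bundles, enforce_inclusion = enforce_inclusion,
                   min_samples = min_samples)
}
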