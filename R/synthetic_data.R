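# Seeded generator of multi-cohort expression + survival studies with known
# prognostic structure. Each cohort gets its own affine (optionally monotone
# nonlinear) distortion of the expression scale, so raw values are not
# comparable across cohorts -- the situation the within-cohort
# dichotomization is designed for. Survival is exponential with the designed
# hazard ratio injected at the group level (above/below the within-cohort
# median), so the designed HR is exactly the estimand of the dichotomized
# pooled analysis.

#' Configure a simulated multi-cohort study
#'
#' @param n_datasets Number of cohorts.
#' @param n_per_dataset Samples per cohort (recycled to `n_datasets`).
#' @param n_genes Genes per cohort (gene ids `g001`, `g002`, ...).
#' @param prognostic_hr Named numeric vector: designed group-level hazard
#'   ratio (high vs low halves) per prognostic gene; names must be gene ids.
#'   HR 1 genes are null. Default: gene `g001` at HR 2.
#' @param baseline_hazard Events per month in the low group.
#' @param censoring_fraction Expected share of censored records, in [0, 1);
#'   censoring is administrative, Uniform(0, tau) with tau solved to hit the
#'   expected share.
#' @param distortion `"affine"` (location shift + positive scale per cohort)
#'   or `"nonlinear"` (affine followed by a strictly increasing cubic bend),
#'   both leaving within-cohort ranks untouched.
#' @param endpoints List (length `n_datasets`) of endpoint subsets carried by
#'   each cohort, or a single character vector applied to all. Default: all
#'   cohorts carry DFS, DDFS and OS.
#' @param covariate_freqs Named list of clinical frequencies: `er_pos`,
#'   `pr_pos`, `her2_pos`, `ln_pos`, `chemo`, `hormone` (probabilities of
#'   pos/yes) and `grade` (probabilities of grades 1:3).
#' @param missingness Probability any clinical field is missing.
#' @param subtype_model Optional `centroid_model`; when given, expression of
#'   the model's genes is generated as centroid + noise per a latent subtype.
#' @param subtype_proportions Mixing proportions over the model's subtypes.
#' @param subtype_noise SD of the noise added to centroids.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_datasets = 5, n_per_dataset = 100, n_genes = 50,
                       prognostic_hr = c(g001 = 2.0),
                       baseline_hazard = 0.02, censoring_fraction = 0.3,
                       distortion = c("affine", "nonlinear"),
                       endpoints = c("DFS", "DDFS", "OS"),
                       covariate_freqs = list(er_pos = 0.7, pr_pos = 0.6,
                                              her2_pos = 0.2, ln_pos = 0.45,
                                              chemo = 0.5, hormone = 0.5,
                                              grade = c(0.2, 0.45, 0.35)),
                       missingness = 0.1,
                       subtype_model = NULL, subtype_proportions = NULL,
                       subtype_noise = 1, seed = 1) {
  distortion <- match.arg(distortion)
  n_per_dataset <- rep_len(as.integer(n_per_dataset), n_datasets)
  if (is.character(endpoints)) endpoints <- rep(list(endpoints), n_datasets)
  stopifnot(n_datasets >= 1L, all(n_per_dataset >= 4L), n_genes >= 1L,
            length(endpoints) == n_datasets,
            all(unlist(endpoints) %in% ENDPOINTS),
            baseline_hazard > 0,
            censoring_fraction >= 0, censoring_fraction < 1,
            missingness >= 0, missingness <= 1)
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  if (length(prognostic_hr) > 0) {
    if (is.null(names(prognostic_hr)) || !all(names(prognostic_hr) %in% gene_ids))
      stop("prognostic_hr must be named by gene ids within the simulated universe")
    if (any(prognostic_hr <= 0)) stop("designed hazard ratios must be > 0")
  }
  if (!is.null(subtype_model)) {
    stopifnot(inherits(subtype_model, "centroid_model"))
    if (is.null(subtype_proportions))
      subtype_proportions <- rep(1 / length(subtype_model$subtypes),
                                 length(subtype_model$subtypes))
    stopifnot(length(subtype_proportions) == length(subtype_model$subtypes),
              abs(sum(subtype_proportions) - 1) < 1e-8)
    if (!all(rownames(subtype_model$table) %in% gene_ids))
      stop("subtype model genes must lie within the simulated gene universe")
  }
  structure(list(n_datasets = n_datasets, n_per_dataset = n_per_dataset,
                 n_genes = n_genes, gene_ids = gene_ids,
                 prognostic_hr = prognostic_hr,
                 baseline_hazard = baseline_hazard,
                 censoring_fraction = censoring_fraction,
                 distortion = distortion, endpoints = endpoints,
                 covariate_freqs = covariate_freqs, missingness = missingness,
                 subtype_model = subtype_model,
                 subtype_proportions = subtype_proportions,
                 subtype_noise = subtype_noise, seed = as.integer(seed)),
            class = "sim_config")
}

# tau such that Uniform(0, tau) censoring yields the expected censored share
# under the subjects' exponential rates
.censoring_horizon <- function(rates, fraction) {
  if (fraction <= 0) return(Inf)
  # P(censored | rate) = P(T > C) = E[exp(-rate * C)] = (1 - e^(-rate tau)) / (rate tau)
  f <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - fraction
  stats::uniroot(f, interval = c(1e-6, 1e6), extendInt = "downX", tol = 1e-10)$root
}

.sim_endpoint <- function(rates, fraction) {
  t_event <- stats::rexp(length(rates), rate = rates)
  if (fraction <= 0) return(list(time = t_event, event = rep(1L, length(rates))))
  tau <- .censoring_horizon(rates, fraction)
  cens <- stats::runif(length(rates), 0, tau)
  list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
}

#' Simulate a multi-cohort study with known prognostic structure
#'
#' Per cohort: baseline expression is standard normal noise (or centroid +
#' noise under a subtype design); each prognostic gene splits the cohort at
#' its within-cohort median, and samples in the upper half draw exponential
#' event times at `baseline_hazard * HR` (multiplicative across prognostic
#' genes), the rest at `baseline_hazard`; censoring is administrative with
#' the configured expected share; the stored expression is the per-cohort
#' distortion of the baseline, so cross-cohort values are incomparable while
#' within-cohort ranks (and hence the designed groups) are preserved.
#'
#' @param cfg A [sim_config()].
#' @return A `study_collection` with an extra `truth` element: `groups`
#'   (data frame of the designed high/low label per prognostic gene and
#'   sample), `hr` (the designed ratios), `subtypes` (latent labels, when a
#'   subtype design is active) and `config`.
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  freqs <- cfg$covariate_freqs
  bundles <- vector("list", cfg$n_datasets)
  truth_groups <- list(); truth_subtypes <- list()
  for (d in seq_len(cfg$n_datasets)) {
    id <- sprintf("D%02d", d)
    n <- cfg$n_per_dataset[d]
    samples <- sprintf("%s_s%04d", id, seq_len(n))
    base <- matrix(stats::rnorm(cfg$n_genes * n), nrow = cfg$n_genes,
                   dimnames = list(cfg$gene_ids, samples))
    sub_lab <- NULL
    if (!is.null(cfg$subtype_model)) {
      sm <- cfg$subtype_model
      sub_lab <- sample(sm$subtypes, n, replace = TRUE,
                        prob = cfg$subtype_proportions)
      g <- rownames(sm$table)
      base[g, ] <- sm$table[, sub_lab, drop = FALSE] +
        cfg$subtype_noise * matrix(stats::rnorm(length(g) * n), nrow = length(g))
      truth_subtypes[[id]] <- data.frame(dataset_id = id, sample_id = samples,
                                         subtype = sub_lab,
                                         stringsAsFactors = FALSE)
    }
    # designed groups from the undistorted values; monotone distortions
    # leave the within-cohort median split unchanged
    rates <- rep(cfg$baseline_hazard, n)
    if (length(cfg$prognostic_hr) > 0) {
      grp <- matrix("", n, length(cfg$prognostic_hr),
                    dimnames = list(NULL, names(cfg$prognostic_hr)))
      for (g in names(cfg$prognostic_hr)) {
        high <- base[g, ] > stats::median(base[g, ])
        rates <- rates * ifelse(high, cfg$prognostic_hr[[g]], 1)
        grp[, g] <- ifelse(high, "high", "low")
      }
      truth_groups[[id]] <- data.frame(dataset_id = id, sample_id = samples,
                                       grp, stringsAsFactors = FALSE,
                                       check.names = FALSE)
    }
    clin <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
    clin$age <- round(stats::rnorm(n, 57, 12), 1)
    clin$size_cm <- round(stats::rlnorm(n, log(2.2), 0.4), 1)
    draw_status <- function(p) ifelse(stats::runif(n) < p, "pos", "neg")
    clin$er_status <- draw_status(freqs$er_pos)
    clin$pr_status <- draw_status(freqs$pr_pos)
    clin$her2_status <- draw_status(freqs$her2_pos)
    clin$ln_status <- draw_status(freqs$ln_pos)
    clin$grade <- sample(1:3, n, replace = TRUE, prob = freqs$grade)
    clin$chemo <- ifelse(stats::runif(n) < freqs$chemo, "yes", "no")
    clin$hormone <- ifelse(stats::runif(n) < freqs$hormone, "yes", "no")
    for (nm in setdiff(names(clin), "sample_id"))
      clin[[nm]][stats::runif(n) < cfg$missingness] <- NA
    for (ep in cfg$endpoints[[d]]) {
      s <- .sim_endpoint(rates, cfg$censoring_fraction)
      clin[[paste0(tolower(ep), "_time")]] <- s$time
      clin[[paste0(tolower(ep), "_event")]] <- s$event
    }
    shift <- stats::runif(1, -3, 3)
    scale <- stats::runif(1, 0.5, 2)
    expr <- shift + scale * base
    if (cfg$distortion == "nonlinear") expr <- expr + 0.15 * expr^3
    bundles[[d]] <- dataset_bundle(gene_matrix(expr, id), clinical_table(clin))
  }
  coll <- build_collection(bundles)
  coll$truth <- list(
    groups = if (length(truth_groups)) do.call(rbind, c(truth_groups, make.row.names = FALSE)) else NULL,
    hr = cfg$prognostic_hr,
    subtypes = if (length(truth_subtypes)) do.call(rbind, c(truth_subtypes, make.row.names = FALSE)) else NULL,
    config = cfg)
  coll
}

#' Simulate a labelled cohort around centroids
#'
#' Each sample is a randomly chosen centroid plus independent Gaussian noise;
#' the latent labels are returned for recovery checks.
#'
#' @param model A `centroid_model`.
#' @param proportions Mixing proportions over the model's subtypes.
#' @param noise Noise standard deviation.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return List with `expr` (genes x samples matrix) and `labels`.
#' @export
simulate_centroid_cohort <- function(model, proportions = NULL, noise = 1,
                                     n = 100, seed = 1) {
  stopifnot(inherits(model, "centroid_model"), n >= 1, noise >= 0)
  if (is.null(proportions))
    proportions <- rep(1 / length(model$subtypes), length(model$subtypes))
  stopifnot(length(proportions) == length(model$subtypes),
            abs(sum(proportions) - 1) < 1e-8)
  set.seed(seed)
  labels <- sample(model$subtypes, n, replace = TRUE, prob = proportions)
  g <- nrow(model$table)
  expr <- model$table[, labels, drop = FALSE] +
    noise * matrix(stats::rnorm(g * n), nrow = g)
  colnames(expr) <- sprintf("s%04d", seq_len(n))
  list(expr = expr, labels = labels)
}

#' Write a study collection as an on-disk fixture
#'
#' Emits, per cohort, the gene-level expression TSV and clinical TSV in the
#' exact formats the readers consume, plus a JSON manifest, closing the loop
#' for end-to-end tests. When the collection carries a simulation truth
#' record, the designed group labels are written alongside as
#' `truth_groups.tsv`.
#'
#' @param collection A `study_collection`.
#' @param out_dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_fixture <- function(collection, out_dir) {
  stopifnot(inherits(collection, "study_collection"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(collection$bundles, function(b) {
    ef <- paste0(b$dataset_id, "_expression.tsv")
    cf <- paste0(b$dataset_id, "_clinical.tsv")
    write_gene_matrix(b$gene_matrix, file.path(out_dir, ef))
    write_clinical_table(b$clinical, file.path(out_dir, cf))
    list(id = b$dataset_id, expression = ef, clinical = cf)
  })
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(datasets = unname(entries)), manifest,
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(collection$truth$groups))
    utils::write.table(collection$truth$groups,
                       file.path(out_dir, "truth_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
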