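# Pooled two-group survival analysis: Kaplan-Meier curves, log-rank test and
# Cox proportional-hazards hazard ratios, via the survival package (Efron tie
# handling throughout).

#' Construct a pooled two-group survival cohort
#'
#' @param time Event/censoring times in months (finite, positive).
#' @param event Event indicators, 0 = censored, 1 = event.
#' @param group Group labels, `"high"` or `"low"`.
#' @param dataset_id Originating dataset per record.
#' @param endpoint One of `"DFS"`, `"DDFS"`, `"OS"`.
#' @return A `pooled_cohort`: data frame (time, event, group, dataset_id)
#'   with the endpoint as an attribute; `group` is a factor with low as the
#'   reference level, so hazard ratios are high vs low.
#' @export
pooled_cohort <- function(time, event, group, dataset_id, endpoint = c("DFS", "DDFS", "OS")) {
  endpoint <- match.arg(endpoint)
  if (length(dataset_id) == 1L) dataset_id <- rep(dataset_id, length(time))
  stopifnot(length(time) == length(event), length(time) == length(group),
            length(time) == length(dataset_id))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and positive")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0/1")
  if (!all(group %in% c("high", "low"))) stop("groups must be 'high'/'low'")
  df <- data.frame(time = as.numeric(time), event = as.integer(event),
                   group = factor(group, levels = c("low", "high")),
                   dataset_id = as.character(dataset_id),
                   stringsAsFactors = FALSE)
  attr(df, "endpoint") <- endpoint
  class(df) <- c("pooled_cohort", "data.frame")
  df
}

#' Per-dataset record counts of a pooled cohort
#'
#' @param cohort A `pooled_cohort`.
#' @return Named integer vector, dataset id -> number of pooled records.
#' @export
per_dataset_n <- function(cohort) {
  tab <- table(cohort$dataset_id)
  stats::setNames(as.integer(tab), names(tab))
}

.check_two_groups <- function(cohort) {
  n <- table(cohort$group)
  if (any(n == 0L))
    stop("single-group cohort: the '", names(n)[n == 0L][1], "' group is empty")
}

#' Kaplan-Meier survival curves for a pooled cohort
#'
#' Product-limit estimates per group: S(t) is the product over event times
#' t_i <= t of (1 - d_i / n_i); subjects censored at an event time are still
#' at risk at that time.
#'
#' @param cohort A `pooled_cohort` with at least one record; curves are
#'   estimated for each group present.
#' @return A `km_curve` data frame: group, time, n_risk, n_event, n_censor,
#'   survival; with the endpoint carried as an attribute.
#' @export
km_estimate <- function(cohort) {
  stopifnot(inherits(cohort, "pooled_cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  cohort$group <- droplevels(cohort$group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = cohort,
                           conf.type = "none")
  strata <- if (is.null(fit$strata)) rep(as.character(cohort$group[1]), length(fit$time))
            else rep(sub("^group=", "", names(fit$strata)), fit$strata)
  out <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv, stringsAsFactors = FALSE)
  attr(out, "endpoint") <- attr(cohort, "endpoint")
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in the high
#' group is compared with its hypergeometric expectation given the risk sets;
#' the statistic is (sum O - E)^2 / sum V, referred to a chi-square with one
#' degree of freedom.
#'
#' @param cohort A `pooled_cohort` with both groups non-empty and at least
#'   one event.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(cohort) {
  stopifnot(inherits(cohort, "pooled_cohort"))
  .check_two_groups(cohort)
  if (sum(cohort$event) == 0L) stop("no events in cohort")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = cohort)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards hazard ratio, high vs low
#'
#' Maximum partial likelihood with the Efron correction for ties. When all
#' events fall in one group the likelihood is monotone (complete separation);
#' the result is then flagged (`separation = TRUE`) and carries an
#' infinite-bound confidence interval rather than an error.
#'
#' @param cohort A `pooled_cohort`.
#' @param stratify_by_dataset Fit a separate baseline hazard per dataset.
#' @param ties Tie handling for the partial likelihood; Efron by default.
#' @return A `test_result` list: `hr`, `ci_low`, `ci_high` (95% Wald),
#'   `beta`, `se`, `wald_p`, `logrank_chi2`, `logrank_p`, `n`, `events`,
#'   `separation`.
#' @export
cox_hr <- function(cohort, stratify_by_dataset = FALSE, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(cohort, "pooled_cohort"))
  .check_two_groups(cohort)
  if (sum(cohort$event) == 0L) stop("no events in cohort")
  ev <- table(cohort$group[cohort$event == 1])
  separation <- any(ev == 0L)
  fml <- if (stratify_by_dataset)
    survival::Surv(time, event) ~ group + survival::strata(dataset_id)
  else survival::Surv(time, event) ~ group
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = cohort, ties = ties)),
    error = function(e) stop("Cox fit failed to converge: ", conditionMessage(e)))
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  lr <- logrank_test(cohort)
  if (separation) {
    res <- list(hr = if (ev[["low"]] == 0L) Inf else 0,
                ci_low = 0, ci_high = Inf,
                beta = beta, se = Inf, wald_p = NA_real_,
                logrank_chi2 = lr$chi2, logrank_p = lr$p,
                n = nrow(cohort), events = sum(cohort$event),
                separation = TRUE)
  } else {
    z <- stats::qnorm(0.975)
    res <- list(hr = exp(beta), ci_low = exp(beta - z * se),
                ci_high = exp(beta + z * se), beta = beta, se = se,
                wald_p = 2 * stats::pnorm(-abs(beta / se)),
                logrank_chi2 = lr$chi2, logrank_p = lr$p,
                n = nrow(cohort), events = sum(cohort$event),
                separation = FALSE)
  }
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("n = %d, events = %d\nHR (high vs low) = %.3g [95%% CI %.3g-%.3g]\nlog-rank chi2 = %.4g, p = %.3g\n",
              x$n, x$events, x$hr, x$ci_low, x$ci_high, x$logrank_chi2, x$logrank_p))
  if (x$separation) cat("NOTE: complete separation (all events in one group)\n")
  invisible(x)
}

#' Pool group assignments and run the survival analysis
#'
#' Builds one pooled cohort from per-dataset high/low assignments: records
#' come only from samples labelled high or low with a complete (time, event)
#' pair for the requested endpoint; datasets lacking the endpoint contribute
#' nothing (with a warning). The pooled cohort is then analysed by
#' [km_estimate()], [logrank_test()] and [cox_hr()]. Pooled n therefore
#' varies with which cohorts measured the gene and carry the endpoint.
#'
#' @param assignments List of `group_assignment` (see [assign_groups()]).
#' @param collection The `study_collection` holding the clinical tables.
#' @param endpoint `"DFS"`, `"DDFS"` or `"OS"`.
#' @param stratify_by_dataset Passed to [cox_hr()].
#' @return List with `cohort` (`pooled_cohort`), `km` (`km_curve`), `result`
#'   (`test_result`) and `per_dataset_n`.
#' @export
analyze_pooled <- function(assignments, collection, endpoint = c("DFS", "DDFS", "OS"),
                           stratify_by_dataset = FALSE) {
  endpoint <- match.arg(endpoint)
  stopifnot(length(assignments) >= 1L, inherits(collection, "study_collection"))
  tcol <- paste0(tolower(endpoint), "_time")
  ecol <- paste0(tolower(endpoint), "_event")
  parts <- list()
  for (a in assignments) {
    b <- collection$bundles[[a$dataset_id]]
    if (is.null(b)) stop("assignment references unknown dataset '", a$dataset_id, "'")
    cl <- b$clinical
    if (!endpoint %in% endpoints_present(cl)) {
      warning("dataset '", a$dataset_id, "' lacks endpoint ", endpoint,
              "; skipped", call. = FALSE)
      next
    }
    lab <- a$labels[cl$sample_id]
    use <- lab %in% c("high", "low") & !is.na(cl[[tcol]]) & !is.na(cl[[ecol]]) &
      cl[[tcol]] > 0
    if (!any(use)) next
    parts[[a$dataset_id]] <- data.frame(
      time = cl[[tcol]][use], event = cl[[ecol]][use],
      group = unname(lab[use]), dataset_id = a$dataset_id,
      stringsAsFactors = FALSE)
  }
  if (length(parts) == 0L)
    stop("no dataset contributes endpoint ", endpoint)
  df <- do.call(rbind, parts)
  cohort <- pooled_cohort(df$time, df$event, df$group, df$dataset_id, endpoint)
  list(cohort = cohort,
       km = km_estimate(cohort),
       result = cox_hr(cohort, stratify_by_dataset = stratify_by_dataset),
       per_dataset_n = per_dataset_n(cohort))
}

#' Benjamini-Hochberg adjustment for multi-marker sweeps
#'
#' Convenience wrapper around [stats::p.adjust()] for adjusting a vector of
#' per-marker log-rank p-values; no adjustment is applied anywhere by
#' default.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
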