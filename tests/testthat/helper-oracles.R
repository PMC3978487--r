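# Independent brute-force oracles for the survival statistics, written
# directly from the defining formulas and kept free of the survival package.

# Product-limit estimator for one group: S(t) over distinct event times.
oracle_km <- function(time, event) {
  stopifnot(length(time) == length(event))
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])          # censored at an event time still at risk
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# Two-group log-rank by direct O/E/V summation over distinct event times.
# Returns the chi-square statistic and the summed variance (for degeneracy
# screening).
oracle_logrank <- function(time, event, group) {
  stopifnot(all(group %in% c("high", "low")))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == "high")
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == "high")
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chi2 = if (v > 0) o_minus_e^2 / v else NA_real_,
       o_minus_e = o_minus_e, v = v)
}

# Small random two-group cohort with events in both the data and a
# non-degenerate log-rank variance (screened by the oracle, not by the
# implementation under test). Ties are encouraged via a coarse time grid.
random_small_cohort <- function(n_max = 12) {
  repeat {
    n <- sample(4:n_max, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    group <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    if (oracle_logrank(time, event, group)$v <= 0) next
    return(pooled_cohort(time, event, group, dataset_id = "D1", endpoint = "DFS"))
  }
}

# Linear-interpolation quantile computed from first principles (order
# statistics + interpolation), independent of stats::quantile.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
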