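test_that("KM estimate reproduces the hand product-limit computation", {
  # one group: times 1,2,3,4,5 with events 1,1,0,1,0
  co <- pooled_cohort(time = 1:5, event = c(1, 1, 0, 1, 0),
                      group = rep("high", 5), dataset_id = "D1")
  km <- km_estimate(co)
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, c(1, 2, 4))
  expect_equal(ev$survival, c(0.8, 0.6, 0.3))

  # all censored: S stays 1
  co2 <- pooled_cohort(1:4, rep(0, 4), rep("low", 4), "D1")
  expect_true(all(km_estimate(co2)$survival == 1))

  # single subject with an event: survival jumps 1 -> 0
  co3 <- pooled_cohort(3, 1, "high", "D1")
  expect_equal(km_estimate(co3)$survival, 0)
})

test_that("KM and log-rank match independent brute-force oracles on random cohorts", {
  set.seed(31)
  for (rep in 1:300) {
    co <- random_small_cohort()
    km <- km_estimate(co)
    for (g in unique(as.character(co$group))) {
      o <- oracle_km(co$time[co$group == g], co$event[co$group == g])
      got <- km[km$group == g & km$n_event > 0, ]
      expect_equal(got$time, o$time, tolerance = 1e-12)
      expect_equal(got$survival, o$survival, tolerance = 1e-12)
    }
    lr <- logrank_test(co)
    o <- oracle_logrank(co$time, co$event, as.character(co$group))
    expect_equal(lr$chi2, o$chi2, tolerance = 1e-12)
    # group-label swap leaves the statistic unchanged
    sw <- pooled_cohort(co$time, co$event,
                        ifelse(co$group == "high", "low", "high"),
                        co$dataset_id)
    expect_equal(logrank_test(sw)$chi2, lr$chi2, tolerance = 1e-12)
  }
})

test_that("identical group compositions give a null log-rank and unit hazard ratio", {
  set.seed(32)
  t0 <- rexp(30, 0.1) + 0.5
  e0 <- rbinom(30, 1, 0.7)
  co <- pooled_cohort(c(t0, t0), c(e0, e0),
                      rep(c("high", "low"), each = 30), "D1")
  lr <- logrank_test(co)
  expect_lt(lr$chi2, 1e-18)
  expect_equal(lr$p, 1)
  r <- cox_hr(co)
  expect_lt(abs(r$beta), 1e-6)
})

test_that("log-rank and Cox error on degenerate cohorts", {
  expect_error(logrank_test(pooled_cohort(1:4, rep(0, 4), rep(c("high", "low"), 2), "D")),
               "no events")
  expect_error(logrank_test(pooled_cohort(1:4, rep(1, 4), rep("high", 4), "D")),
               "single-group")
  # complete separation: flagged, not a crash
  co <- pooled_cohort(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0),
                      rep(c("high", "low"), each = 3), "D")
  r <- cox_hr(co)
  expect_true(r$separation)
  expect_equal(r$ci_low, 0)
  expect_equal(r$ci_high, Inf)
})

test_that("Cox obeys label-swap and time-rescaling identities", {
  set.seed(33)
  for (rep in 1:10) {
    co <- local({
      n <- 60
      g <- rep(c("high", "low"), each = n / 2)
      t <- rexp(n, ifelse(g == "high", 0.04, 0.02)) + 0.01
      e <- rbinom(n, 1, 0.75)
      if (sum(e[g == "high"]) == 0 || sum(e[g == "low"]) == 0) return(NULL)
      pooled_cohort(t, e, g, "D1")
    })
    if (is.null(co)) next
    r <- cox_hr(co)
    sw <- pooled_cohort(co$time, co$event,
                        ifelse(co$group == "high", "low", "high"), co$dataset_id)
    expect_equal(cox_hr(sw)$hr, 1 / r$hr, tolerance = 1e-8)
    sc <- pooled_cohort(co$time * 37.5, co$event, as.character(co$group),
                        co$dataset_id)
    expect_equal(cox_hr(sc)$beta, r$beta, tolerance = 1e-10)
    expect_equal(logrank_test(sc)$chi2, logrank_test(co)$chi2, tolerance = 1e-12)
  }
})

test_that("duplicating a cohort keeps the hazard ratio and shrinks the CI", {
  set.seed(34)
  n <- 80
  g <- rep(c("high", "low"), each = n / 2)
  t <- rexp(n, ifelse(g == "high", 0.05, 0.025))
  e <- rbinom(n, 1, 0.8)
  co <- pooled_cohort(t, e, g, "D1")
  co2 <- pooled_cohort(c(t, t), c(e, e), c(g, g), rep(c("D1", "D2"), each = n))
  # under the Breslow likelihood duplication rescales the log-likelihood
  r1 <- cox_hr(co, ties = "breslow")
  r2 <- cox_hr(co2, ties = "breslow")
  expect_equal(r2$hr, r1$hr, tolerance = 1e-6)
  expect_lt(r2$ci_high - r2$ci_low, r1$ci_high - r1$ci_low)
  # Efron handling agrees closely even though duplication introduces ties
  expect_equal(cox_hr(co2)$hr, cox_hr(co)$hr, tolerance = 0.05)
})

test_that("pooled analysis reduces to the direct pipeline on one dataset", {
  set.seed(35)
  v <- matrix(rnorm(60), 3, dimnames = list(c("g1", "g2", "g3"), NULL))
  b <- make_bundle("D1", v, rexp(20, 0.05) + 0.1, rbinom(20, 1, 0.8))
  coll <- build_collection(list(b))
  asg <- assign_groups(coll, "g1")
  out <- analyze_pooled(asg, coll, "DFS")
  lab <- asg$D1$labels
  keep <- lab %in% c("high", "low")
  direct <- pooled_cohort(b$clinical$dfs_time[keep], b$clinical$dfs_event[keep],
                          lab[keep], "D1")
  expect_equal(out$result$hr, cox_hr(direct)$hr)
  expect_equal(out$result$logrank_chi2, logrank_test(direct)$chi2)
  expect_equal(out$per_dataset_n, c(D1 = 20L))
})

test_that("datasets lacking the endpoint contribute nothing to the pool", {
  set.seed(36)
  v1 <- matrix(rnorm(60), 3, dimnames = list(c("g1", "g2", "g3"), NULL))
  v2 <- matrix(rnorm(60), 3, dimnames = list(c("g1", "g2", "g3"), NULL))
  b1 <- make_bundle("D1", v1, rexp(20, 0.05) + 0.1, rbinom(20, 1, 0.8))
  # D2 carries OS only
  clin2 <- data.frame(sample_id = sprintf("D2_s%02d", 1:20),
                      os_time = rexp(20, 0.05) + 0.1,
                      os_event = rbinom(20, 1, 0.8))
  colnames(v2) <- clin2$sample_id
  b2 <- dataset_bundle(gene_matrix(v2, "D2"), clinical_table(clin2))
  coll <- build_collection(list(b1, b2))
  asg <- assign_groups(coll, "g1")
  expect_warning(out <- analyze_pooled(asg, coll, "DFS"), "lacks endpoint DFS")
  expect_equal(sum(out$per_dataset_n), 20L)
  expect_named(out$per_dataset_n, "D1")
})

test_that("single-group pools are rejected after exclusions", {
  v <- matrix(c(5, 5, 5, 5), 1, dimnames = list("g1", NULL))
  b <- make_bundle("D1", v, rep(10, 4), rep(1, 4))
  coll <- build_collection(list(b))
  asg <- assign_groups(coll, "g1")   # constant gene: everyone low
  expect_error(analyze_pooled(asg, coll, "DFS"), "single-group")
})
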