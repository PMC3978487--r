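# poolmark

Cross-dataset prognostic marker screening for expression cohorts, in R.

Public breast cancer expression cohorts come from many microarray
platforms, so their values are not directly comparable and cannot honestly
be pooled or batch-corrected into one matrix. `poolmark` implements the
pooled-dichotomization design used by survival-query biomarker engines:

1. within each cohort, split samples into **high**/**low** expressors of a
   query gene at that cohort's median (or upper/lower quartile) — a step
   that depends only on within-cohort ranks, so platform location/scale
   effects cancel by construction;
2. pool the group labels (never the values) across cohorts into one
   two-group survival cohort for DFS, DDFS or OS;
3. analyse it with the Kaplan-Meier estimator, the two-group log-rank test,
   and a Cox proportional-hazards fit (Efron ties) reporting the hazard
   ratio of high vs low with a 95% CI:

   HR = exp(β̂),  β̂ = argmax of the Cox partial likelihood for
   group(high) = 1, with the log-rank statistic (ΣO−E)²/ΣV as the headline
   test.

Around that core: clinical filtering (ER/PR/HER2, nodal status, grade, age,
size, treatment), molecular-subtype stratification via a generic
nearest-centroid classifier with pluggable centroid tables (ssp2003 /
ssp2006 / pam50 roles), multi-marker combination (`all_high`: above-median
for *every* marker), a consensus sweep (significant when log-rank p < 0.05
in ≥ 2 of 3 classifiers), miRNA queries through intronic host-gene
expression as a proxy, and a seeded multi-cohort simulator with known
prognostic structure for calibration and testing.

## Worked example

Simulate a five-cohort study (cohort sizes 60–440, one prognostic gene
`g001` with a designed group hazard ratio of 2) and query it:

```r
library(poolmark)

cfg  <- sim_config(n_datasets = 5, n_per_dataset = c(60, 100, 150, 250, 440),
                   n_genes = 50, prognostic_hr = c(g001 = 2.0), seed = 20)
coll <- simulate_collection(cfg)
coll
#> study_collection: 5 datasets, 1000 samples, 50 genes in universe

res <- run_query(coll, query_spec("g001", endpoint = "DFS"))
res
#> Marker query: g001 | DFS | median
#> n = 1000, events = 677
#> HR (high vs low) = 2.05 [95% CI 1.75-2.39]
#> log-rank chi2 = 85.53, p = 2.28e-20
#> datasets: D01 (60), D02 (100), D03 (150), D04 (250), D05 (440)
```

All 1000 samples contribute because every cohort measures `g001` and
carries DFS; the pooled high group's hazard is estimated at 2.05 times the
low group's (design: 2.0), and the log-rank test rejects overwhelmingly. A
null gene from the same study shows what no signal looks like:

```r
run_query(coll, query_spec("g042", endpoint = "DFS"))$result
#> n = 1000, events = 677
#> HR (high vs low) = 1.07 [95% CI 0.916-1.24]
#> log-rank chi2 = 0.6772, p = 0.411
```

`plot(res)` draws the two Kaplan-Meier curves with n, HR and p annotated.
Real data enter through a JSON/YAML manifest listing per-cohort expression
TSVs (probe- or gene-level, with an optional probe→gene annotation),
clinical TSVs, and are read with `read_collection()`; see the vignette for
formats, filters, subtype sweeps and the miRNA host-gene interface.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/poolmark.R simulate --out fix --seed 9
Rscript inst/cli/poolmark.R analyze --manifest fix/manifest.json \
    --genes g001 --endpoint dfs --cutoff median --out results.tsv
```

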