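---
title: "Pooled survival meta-analysis of dichotomized expression markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled survival meta-analysis of dichotomized expression markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmark)
```

## The problem

Prognostic value of a gene's expression in breast cancer is usually asked of
many public microarray cohorts at once. Those cohorts were measured on
different platforms with different dynamic ranges and normalizations, so
their expression values are not comparable: pooling raw values, or
normalizing across cohorts, imports platform artefacts directly into the
survival model. `poolmark` takes the alternative route used by web-based
biomarker query engines: **dichotomize within each cohort, pool the group
labels**. Each cohort is split into high and low expressors at its own
median (or quartile), a step that depends only on within-cohort ranks; the
resulting labels are then concatenated across cohorts into a single
two-group survival analysis. Study-specific location and scale effects are
"negated" by construction, because any strictly increasing transform of a
cohort's values leaves its labels unchanged. That invariance is the formal
backbone of the design and is tested explicitly, both at the labelling
level and end-to-end.

The price of this design is deliberate: dichotomization discards
within-group dose information, and an unstratified pooled model assumes a
shared baseline hazard across cohorts. A dataset-stratified Cox fit
(`stratify_by_dataset = TRUE`) is available for users worried about the
latter.

## The pipeline

For a query on gene $g$, endpoint $e \in \{\mathrm{DFS}, \mathrm{DDFS},
\mathrm{OS}\}$:

1. **Gene centering** (once per cohort): probes mapping to more than one
   gene are discarded; multiple probes for one gene are averaged per sample,
   arithmetically on the stored log scale. Averaging on the log scale is a
   choice; the inputs are post-normalization log intensities and the
   geometric/arithmetic distinction is immaterial to the rank-based steps
   downstream.
2. **Inclusion**: cohorts need survival information and at least
   `min_samples` patients (default 48). This is a curation policy, not
   mathematics, and is a plain parameter.
3. **Clinical filtering**: a sample passes a `filter_spec` iff it satisfies
   every stated constraint; a missing value in a *constrained* field
   excludes the sample, while unconstrained fields never do. This maximizes
   usable n without biasing unconstrained queries.
4. **Subtype stratification** (optional): nearest-centroid calls on the full
   cohort, then restriction to one subtype. Labels are sample-intrinsic, so
   classification before filtering is well-defined and is the order used.
5. **Dichotomization**: labels per the cut-off rule below; samples with
   missing expression are excluded. For multi-marker queries the per-gene
   labels combine by `all_high` (high iff high for every marker) or its
   `all_low` mirror; a cohort must measure *all* queried genes to
   contribute, otherwise the combined group would mean different things in
   different cohorts.
6. **Pooling and analysis**: records (time, event, group, cohort) from all
   contributing cohorts feed one Kaplan-Meier estimate per group, the
   two-group log-rank test, and a Cox proportional-hazards fit coded high =
   1, so HR > 1 means worse outcome for high expressors. The headline
   p-value is the log-rank p; the Cox Wald p travels in the detailed record.

## Cut-off rules and ties

All cut-offs are linear-interpolation quantiles (type 7) of the non-missing
values:

* `median` — high iff value **strictly greater** than the median; ties at
  the cut-off go low. With distinct values this yields exactly
  $\lfloor n/2 \rfloor$ high.
* `upper_quartile` — high iff strictly above the 75th percentile (top
  quarter vs the rest).
* `lower_quartile` — low iff strictly below the 25th percentile (bottom
  quarter vs the rest).

Strict inequality for the high group follows the "greater than median
expression" convention; the quartile rules are dichotomies, not
trichotomies, so each produces exactly two groups. The quantile estimator is
a documented choice, backed by a first-principles interpolation oracle in
the tests; any estimator lying between adjacent order statistics would give
identical labels on the data points themselves, which is why monotone
invariance holds regardless.

Whether the original engines computed cut-offs before or after clinical
filtering is not documented anywhere we could check; both orders are
provided (`cutoff_scope = "filtered"`, the default, or `"full"`), and
neither is asserted to be the historical behaviour.

## Survival machinery

Kaplan-Meier estimation, the log-rank test and Cox regression are standard
and are delegated to the `survival` package (product-limit estimator;
(O−E)²/V log-rank; Efron tie correction, `survival`'s default, for the
partial likelihood). The test suite holds this machinery against
independent brute-force oracles written directly from the defining
formulas — product-limit products and hypergeometric O/E/V sums over event
times — with agreement required at 1e-12 on a thousand random small
cohorts, plus analytic identities: unit HR on duplicated groups, exact
reciprocal HR under label swap, invariance of the coefficient under time
rescaling (times are months and are never rescaled internally).

Complete separation (all events in one group) makes the partial likelihood
monotone; the result is then flagged (`separation = TRUE`) with an
infinite-bound CI rather than raised as an error, since a screening sweep
must survive degenerate cells. Sweep cells that fail outright (an endpoint
absent from every cohort, say) are emitted as NA cells and still count as
attempted classifiers in the consensus denominator.

No multiple-testing correction is applied within a single-marker analysis;
`adjust_bh()` (Benjamini-Hochberg) is available for sweeps and off by
default.

## Subtype classification

`centroid_model` is a generic single-sample nearest-centroid classifier
with pluggable centroid tables, covering the ssp2003 / ssp2006 / pam50
roles. Published centroid tables are data, not code: the package documents
the TSV schema (`gene_id` column plus one column per subtype) and ships
only synthetic fixture models in its tests. Choices:

* **Spearman correlation by default** (Pearson per model), consistent with
  the single-sample-predictor lineage and invariant to monotone transforms
  of the profile — the same invariance the rest of the pipeline relies on.
* **Unclassified** when fewer than `min_genes = 10` model genes are
  measured (guarding against spurious correlations on tiny overlaps) or
  when the best correlation is ≤ 0. The reference implementations do not
  surface their internal rule; ours is conservative and documented rather
  than guessed to be identical. Numerical equivalence with `genefu` is
  therefore not claimed; recovery is demonstrated on fixture models of
  three distinct geometries (block-orthogonal, shifted, correlated-core).
* **Ties** break by the model's subtype column order, deterministically.

The consensus rule for sweeps is the screening convention: a marker is
significant for a (gene, endpoint, cut-off) when log-rank p < 0.05
(strictly) under at least two of the three classifiers; both constants are
parameters.

## miRNA host-gene proxy

Intragenic miRNAs can be read through their host gene's expression on
conventional arrays. `run_mirna_query()` resolves a miRNA against a
user-supplied host map (pinned to a miRBase/Ensembl release; no live
lookup) and delegates to the gene pipeline. Multi-host miRNAs yield one
result per host gene — averaging across hosts would invent a quantity no
platform measured. Every result row carries `proxy = TRUE` because host and
miRNA are not always co-expressed; the proxy is an assumption, not a
measurement.

## The synthetic study generator

`simulate_collection()` exists so that every pipeline stage is testable
without downloading cohorts. What it emulates:

* **Cross-platform incomparability**: each cohort's expression is a
  location/scale distortion (optionally a strictly increasing nonlinear
  bend) of baseline noise, so raw values are useless across cohorts while
  within-cohort ranks are intact.
* **A known estimand**: for each designated prognostic gene, samples above
  their cohort's median draw exponential event times at `baseline_hazard *
  HR`, others at `baseline_hazard` (multiplicative across prognostic
  genes). Injecting the effect at the group level makes the designed HR
  *exactly* the estimand of the dichotomized pooled analysis, with no
  attenuation bookkeeping; a continuous-effect design would recover a
  smaller group HR and obscure calibration checks.
* **Censoring**: administrative, `Uniform(0, tau)`, with `tau` solved
  numerically so the expected censored share equals `censoring_fraction`
  under the designed rate mixture.
* **Clinical structure**: covariate frequencies roughly matching published
  breast cancer cohort summaries (ER+ ≈ 70%, PR+ ≈ 60%, HER2+ ≈ 20%,
  node-positive ≈ 45%, grade 1/2/3 ≈ 20/45/35%), with 10% missingness by
  default; endpoints can be given per cohort to emulate the uneven
  availability of DFS/DDFS/OS in public data.
* Default study shape: 5 cohorts of 100 samples, 50 genes, one prognostic
  gene at HR 2, baseline hazard 0.02 events/month (median survival ≈ 35
  months in the low group), 30% censoring — a desk-scale caricature of a
  multi-cohort breast cancer compendium.

What it does **not** emulate: probe-level chemistry, correlated gene-gene
structure (beyond the optional centroid design), informative censoring,
cure fractions, or non-proportional hazards. Passing tests on this
generator shows the pipeline computes what it claims on data satisfying its
own assumptions; it does not validate the biological proxy assumptions or
the clinical meaning of any marker.

## Problem sizes and tolerances in the test suite

The suite runs at desk scale: a thousand random cohorts of n ≤ 12 for the
oracle equivalences (exact to 1e-12); 200 replicates of a 5-cohort, pooled
n = 2000, 30%-censored study for HR recovery (mean within [1.9, 2.1] at
designed HR 2); 500 seeded replicates of a 3-cohort null study for type-I
error (rejection rate within the 99% binomial band around 0.05); 100
randomized trials for monotone invariance (bit-identical labels); 200 draws
per centroid geometry for subtype recovery (≥95% at noise SD 0.5, SD 3
block separation; 100% at zero noise). `scripts/acceptance.R` recomputes
the same families of quantities from scratch at comparable sizes.

## Known limitations

* The pooled model is a two-group Cox fit; clinical covariates filter
  samples but are never regression adjusters (matching the query-engine
  design this follows), so confounding by cohort composition is possible
  and intentional to the method being modelled.
* Median splits at small n are coarse; cohorts whose filtered subset has a
  degenerate expression distribution are skipped with a warning.
* Host-gene proxying inherits every caveat of miRNA-host co-expression.
* Subtype calls on cohorts sharing few genes with a centroid model go
  `unclassified` wholesale rather than being guessed.
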