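test_that("expression matrix reader enforces shape and id invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2",
               "A_01\t1.5\t2.5",
               "A_02\t3\tNA",
               "A_03\t-1\t0.25"), f)
  pm <- read_expression_matrix(f, "D1")
  expect_s3_class(pm, "probe_matrix")
  expect_equal(dim(pm$values), c(3L, 2L))
  expect_equal(pm$values["A_02", "s2"], NA_real_)
  expect_equal(pm$values["A_01", ], c(s1 = 1.5, s2 = 2.5))

  writeLines(c("probe_id\ts1", "A_01\t1", "A_01\t2"), f)
  expect_error(read_expression_matrix(f, "D1"), "A_01")

  writeLines(character(0), f)
  expect_error(read_expression_matrix(f, "D1"), "no probes")

  writeLines(c("probe_id\ts1\ts2", "A_01\t1\toops"), f)
  expect_error(read_expression_matrix(f, "D1"), "A_01.*s2|s2.*A_01")
})

test_that("clinical reader normalizes enumerations and endpoint pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ter_status\tgrade\tdfs_time\tdfs_event\tos_time\tos_event\textra",
               "s1\tPositive\t2\t60\t1\t80\t0\tx",
               "s2\t1\t4\t\t1\t50\t1\ty",
               "s3\tneg\t3\t12.5\t0\tNA\tNA\tz"), f)
  expect_warning(expect_warning(ct <- read_clinical_table(f), "grade"), "DFS")
  expect_equal(ct$er_status, c("pos", "pos", "neg"))
  expect_equal(ct$grade, c(2L, NA, 3L))
  # event without time: both coerced to missing
  expect_true(is.na(ct$dfs_time[2]) && is.na(ct$dfs_event[2]))
  expect_equal(ct$dfs_time[1], 60)
  expect_equal(endpoints_present(ct), c("DFS", "OS"))
  expect_false("extra" %in% names(ct))

  writeLines(c("id\ter\n", "s1\tpos"), f)
  expect_error(read_clinical_table(f), "sample_id")
})

test_that("unknown categorical tokens become missing with a warning, never an error", {
  df <- data.frame(sample_id = c("a", "b"), er_status = c("equivocal", "pos"))
  expect_warning(ct <- clinical_table(df), "equivocal")
  expect_equal(ct$er_status, c(NA, "pos"))
})

test_that("gene centering drops multi-gene probes and averages the rest", {
  v <- matrix(c(2, 4, 4, 6, 9, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  pm <- probe_matrix(v, "D1")
  ann <- probe_annotation(c("A", "B", "C", "C"), c("g1", "g1", "g1", "g2"))
  gm <- gene_center(pm, ann)
  expect_equal(rownames(gm$values), "g1")       # C discarded, so g2 absent
  expect_equal(unname(gm$values["g1", ]), c(3, 5))

  # single-probe gene: identity
  ann1 <- probe_annotation("A", "g1")
  gm1 <- gene_center(pm, ann1)
  expect_equal(gm1$values["g1", ], v["A", ])

  # mean over available values when cells are missing
  v2 <- matrix(c(2, NA, 4, 6), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  gm2 <- gene_center(probe_matrix(v2, "D1"), probe_annotation(c("A", "B"), c("g1", "g1")))
  expect_equal(unname(gm2$values["g1", ]), c(3, 6))

  expect_error(gene_center(pm, probe_annotation("ZZZ", "g9")), "no mappable probes")
})

test_that("gene centering is idempotent and bounded by contributing probes", {
  set.seed(11)
  for (rep in 1:20) {
    np <- sample(4:12, 1); ns <- sample(2:6, 1)
    v <- matrix(rnorm(np * ns), np,
                dimnames = list(sprintf("p%02d", 1:np), sprintf("s%d", 1:ns)))
    v[sample(length(v), size = round(0.1 * length(v)))] <- NA
    genes <- sprintf("g%d", sample(1:3, np, replace = TRUE))
    ann <- probe_annotation(rownames(v), genes)
    gm <- tryCatch(gene_center(probe_matrix(v, "D"), ann), error = function(e) NULL)
    if (is.null(gm)) next
    # bounds: per sample, each gene mean lies within its probes' range
    for (g in rownames(gm$values)) {
      contrib <- v[genes == g, , drop = FALSE]
      for (s in colnames(v)) {
        x <- contrib[, s]; m <- gm$values[g, s]
        if (all(is.na(x))) expect_true(is.na(m))
        else expect_true(m >= min(x, na.rm = TRUE) - 1e-12 &&
                         m <= max(x, na.rm = TRUE) + 1e-12)
      }
    }
    # idempotence under the identity annotation
    id_ann <- probe_annotation(rownames(gm$values), rownames(gm$values))
    pm2 <- probe_matrix(gm$values, "D")
    expect_identical(gene_center(pm2, id_ann)$values, gm$values)
  }
})

test_that("the 48-sample inclusion rule is a sharp boundary", {
  mk <- function(n, with_dfs = TRUE) {
    v <- matrix(rnorm(2 * n), 2)
    make_bundle("Dx", v,
                dfs_time = if (with_dfs) rep(10, n) else NULL,
                dfs_event = if (with_dfs) rep(1, n) else NULL)
  }
  expect_true(validate_dataset(mk(48))$passes_inclusion)
  expect_false(validate_dataset(mk(47))$passes_inclusion)
  r <- validate_dataset(mk(100, with_dfs = FALSE))
  expect_false(r$passes_inclusion)
  expect_match(paste(r$messages, collapse = " "), "no survival information")
  expect_true(validate_dataset(mk(47), min_samples = 40)$passes_inclusion)
})

test_that("collections take the exact gene-id union and reject duplicate ids", {
  b1 <- make_bundle("D1", matrix(rnorm(8), 2, dimnames = list(c("g1", "g2"), NULL)),
                    rep(5, 4), rep(1, 4))
  b2 <- make_bundle("D2", matrix(rnorm(8), 2, dimnames = list(c("g2", "g3"), NULL)),
                    rep(5, 4), rep(1, 4))
  coll <- build_collection(list(b1, b2))
  expect_setequal(coll$gene_universe, c("g1", "g2", "g3"))
  expect_equal(build_collection(list(b1))$gene_universe, c("g1", "g2"))
  b1b <- make_bundle("D1", matrix(rnorm(4), 2), rep(5, 2), rep(1, 2))
  expect_error(build_collection(list(b1, b1b)), "duplicate dataset id")
  expect_warning(c2 <- build_collection(list(b1, b2), enforce_inclusion = TRUE,
                                        min_samples = 3), NA)
  expect_warning(expect_error(
    build_collection(list(b1), enforce_inclusion = TRUE, min_samples = 50),
    "all datasets excluded"), "excluded")
})

test_that("gene matrix and clinical table round-trip through TSV exactly", {
  set.seed(3)
  v <- matrix(rnorm(12) * 10^sample(-3:3, 12, TRUE), 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4")))
  v[2, 3] <- NA
  gm <- gene_matrix(v, "D1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_matrix(gm, f)
  gm2 <- read_expression_matrix(f, "D1")
  expect_s3_class(gm2, "gene_matrix")   # header announces gene_id
  expect_identical(gm2$values, v)

  ct <- clinical_table(data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    age = c(51.3, NA, 67.8, 44),
    er_status = c("pos", "neg", NA, "pos"),
    grade = c(1, 2, 3, NA),
    dfs_time = c(12.25, 60, NA, 1 / 3),
    dfs_event = c(1, 0, NA, 1)))
  write_clinical_table(ct, f)
  ct2 <- read_clinical_table(f)
  expect_identical(ct2, ct)
})

test_that("manifest reader rebuilds a collection, gene-centering when annotated", {
  dir <- withr::local_tempdir()
  # probe-level dataset with annotation
  writeLines(c("probe_id\ts1\ts2\ts3\ts4",
               "p1\t1\t2\t3\t4", "p2\t3\t4\t5\t6", "p3\t9\t9\t9\t9"),
             file.path(dir, "expr1.tsv"))
  writeLines(c("probe_id\tgene_id", "p1\tg1", "p2\tg1", "p3\tg1", "p3\tg2"),
             file.path(dir, "ann1.tsv"))
  writeLines(c("sample_id\tdfs_time\tdfs_event",
               "s1\t10\t1", "s2\t20\t0", "s3\t30\t1", "s4\t40\t0"),
             file.path(dir, "clin1.tsv"))
  jsonlite::write_json(list(datasets = list(list(
    id = "D1", expression = "expr1.tsv", clinical = "clin1.tsv",
    annotation = "ann1.tsv"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  coll <- read_collection(file.path(dir, "manifest.json"))
  expect_equal(coll$gene_universe, "g1")
  expect_equal(unname(coll$bundles$D1$gene_matrix$values["g1", ]), c(2, 3, 4, 5))
})
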