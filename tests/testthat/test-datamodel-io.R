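test_that("expression matrix construction enforces its invariants", {
  v <- matrix(rnorm(6), 2, 3)
  m <- expression_matrix(v, c("f1", "f2"), c("s1", "s2", "s3"))
  expect_identical(dim(m), c(2L, 3L))
  expect_error(expression_matrix(v, c("f1", "f1"), c("s1", "s2", "s3")),
               "duplicate feature ID: f1")
  expect_error(expression_matrix(v, c("f1", "f2"), c("s1", "s1", "s3")),
               "duplicate sample ID: s1")
  v[2, 3] <- NA
  expect_error(expression_matrix(v, c("f1", "f2"), c("s1", "s2", "s3")),
               "non-finite value at feature 'f2', sample 's3'")
})

test_that("plain TSV write/read round trip is bit-exact", {
  set.seed(42)
  m <- expression_matrix(matrix(rnorm(12) * 10^sample(-3:3, 12, TRUE), 3, 4),
                         sprintf("feat%d", 1:3), sprintf("s%d", 1:4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path, format = "plain_tsv")
  expect_identical(back$feature_ids, m$feature_ids)
  expect_identical(back$sample_ids, m$sample_ids)
  expect_identical(back$values, m$values)
})

test_that("series-matrix dialect skips metadata and strips quotes", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "!Series_title\t\"a synthetic series\"",
    "!Series_platform_id\tGPL00000",
    "!series_matrix_table_begin",
    paste("\"ID_REF\"", "\"GSM1\"", "\"GSM2\"", "\"GSM3\"", "\"GSM4\"",
          sep = "\t"),
    paste("\"mA\"", "1.5", "2", "3.25", "4", sep = "\t"),
    paste("\"mB\"", "0.5", "0.25", "0.125", "1", sep = "\t"),
    paste("\"mC\"", "7", "8", "9", "10", sep = "\t"),
    "!series_matrix_table_end",
    "!Series_footer\tignored"), path)
  m <- read_expression_matrix(path)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(m$feature_ids, c("mA", "mB", "mC"))
  expect_identical(m$sample_ids, c("GSM1", "GSM2", "GSM3", "GSM4"))
  expect_identical(m$values["mB", "GSM3"], 0.125)
})

test_that("malformed matrix files raise located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "fA\t1\t2", "fA\t3\t4"), path)
  expect_error(read_expression_matrix(path), "duplicate feature ID: fA")
  writeLines(c("feature_id\ts1\ts2", "fA\t1\tok"), path)
  expect_error(read_expression_matrix(path),
               "non-numeric value 'ok' at feature 'fA', sample 's2'")
})

test_that("cohort label IO round trips and validates status codes", {
  lab <- cohort_labels(c("a", "b", "c"), c(1, 0, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_labels(lab, path)
  back <- read_cohort_labels(path)
  expect_identical(back$status, lab$status)
  writeLines(c("sample_id\tstatus", "a\t2"), path)
  expect_error(read_cohort_labels(path), "invalid status '2'")
  expect_error(cohort_labels(c("a", "a"), c(0, 1)), "duplicate sample ID")
})

test_that("stratified 2:1 split reproduces the canonical cohort counts", {
  lab <- cohort_labels(sprintf("p%04d", 1:3974),
                       c(rep(1L, 1288), rep(0L, 2686)))
  sp <- stratified_split(lab, c(2, 1), seed = 11)
  tr_status <- lab$status[sp$train_ids]
  va_status <- lab$status[sp$validation_ids]
  expect_identical(sum(tr_status == 1L), 859L)
  expect_identical(sum(tr_status == 0L), 1791L)
  expect_identical(sum(va_status == 1L), 429L)
  expect_identical(sum(va_status == 0L), 895L)
})

test_that("split rounding rule and partition invariants hold", {
  lab <- cohort_labels(sprintf("s%d", 1:9), c(rep(1L, 6), rep(0L, 3)))
  sp <- stratified_split(lab, c(2, 1), seed = 1)
  expect_identical(sum(lab$status[sp$train_ids] == 1L), 4L)
  expect_identical(sum(lab$status[sp$train_ids] == 0L), 2L)

  set.seed(99)
  for (seed in 1:5) {
    n1 <- sample(20:200, 1)
    n0 <- sample(20:200, 1)
    ratio <- sample(1:4, 2, replace = TRUE)
    lab <- cohort_labels(sprintf("x%d", seq_len(n1 + n0)),
                         c(rep(1L, n1), rep(0L, n0)))
    sp <- stratified_split(lab, ratio, seed)
    expect_setequal(c(sp$train_ids, sp$validation_ids), lab$sample_ids)
    expect_length(intersect(sp$train_ids, sp$validation_ids), 0)
    expect_identical(sum(lab$status[sp$train_ids] == 1L),
                     as.integer(floor(n1 * ratio[1] / sum(ratio) + 0.5)))
    expect_identical(sum(lab$status[sp$train_ids] == 0L),
                     as.integer(floor(n0 * ratio[1] / sum(ratio) + 0.5)))
  }
})

test_that("split is seed-reproducible and seed-sensitive", {
  lab <- cohort_labels(sprintf("s%d", 1:60), rep(c(1L, 0L), 30))
  a <- stratified_split(lab, c(2, 1), seed = 7)
  b <- stratified_split(lab, c(2, 1), seed = 7)
  c <- stratified_split(lab, c(2, 1), seed = 8)
  expect_identical(a, b)
  expect_false(identical(sort(a$train_ids), sort(c$train_ids)) &&
                 identical(a$train_ids, c$train_ids))
  expect_error(stratified_split(cohort_labels(c("a", "b"), c(1, 0))),
               "cannot stratify")
  path <- withr::local_tempfile(fileext = ".json")
  write_split(a, path)
  expect_identical(read_split(path), a)
})

test_that("normalization fits on training only, clips, and hits 0/1", {
  m <- expression_matrix(rbind(c(2, 4, 6, 8), c(1, 2, 3, -5)),
                         c("fA", "fB"), c("s1", "s2", "s3", "s4"))
  params <- fit_normalization(m, c("s1", "s2", "s3"))
  expect_equal(unname(params$min), c(2, 1))
  expect_equal(unname(params$max), c(6, 3))

  norm <- apply_normalization(m, params)
  expect_equal(unname(norm$values["fA", ]), c(0, 0.5, 1, 1)) # 8 clipped
  expect_equal(unname(norm$values["fB", "s4"]), 0)            # -5 clipped

  # own fitting partition attains both boundaries exactly, per feature
  own <- apply_normalization(subset_matrix(m, samples = c("s1", "s2", "s3")),
                             params)
  expect_true(all(apply(own$values, 1, min) == 0))
  expect_true(all(apply(own$values, 1, max) == 1))

  const <- expression_matrix(rbind(c(5, 5, 5)), "fC", c("s1", "s2", "s3"))
  expect_error(fit_normalization(const, c("s1", "s2", "s3")),
               "'fC' is constant")
  expect_error(apply_normalization(const, params), "missing from")
})
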