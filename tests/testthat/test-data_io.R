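test_that("a well-formed matrix file reads with the expected geometry", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2",
               "cg1\t0.1\t0.2",
               "cg2\t0.3\tNA",
               "cg3\t0.5\t0.6"), path)
  m <- read_feature_matrix(path, "methylation")
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("cg1", "cg2", "cg3"))
  expect_identical(colnames(m), c("s1", "s2"))
  expect_true(is.na(m["cg2", "s2"]))
})

test_that("the header's leading id cell is optional", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\ts2", "cg1\t0.1\t0.2"), path)
  m <- read_feature_matrix(path, "methylation")
  expect_identical(colnames(m), c("s1", "s2"))
})

test_that("ragged rows are rejected with the offending line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "cg1\t0.1", "cg2\t0.3\t0.4"), path)
  expect_error(read_feature_matrix(path, "methylation"), "line 2")
})

test_that("kind-specific range validation names the offending cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "cg1\t0.1\t1.3"), path)
  expect_error(read_feature_matrix(path, "methylation"), "cg1/s2")
  expect_silent(read_feature_matrix(path, "methylation",
                                    validate_range = FALSE))

  gpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "rs1\t0\t1.5"), gpath)
  expect_error(read_feature_matrix(gpath, "genotype"), "rs1/s2")
  expect_silent(read_feature_matrix(gpath, "genotype", dosage = TRUE))
})

test_that("duplicate IDs and non-numeric cells are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts1", "cg1\t0.1\t0.2"), path)
  expect_error(read_feature_matrix(path, "methylation"),
               "duplicate sample")
  writeLines(c("id\ts1\ts2", "cg1\t0.1\t0.2", "cg1\t0.1\t0.2"), path)
  expect_error(read_feature_matrix(path, "methylation"),
               "duplicate feature")
  writeLines(c("id\ts1\ts2", "cg1\t0.1\tzero"), path)
  expect_error(read_feature_matrix(path, "methylation"), "non-numeric")
})

test_that("write/read round trip is bit-exact, missing cells included", {
  set.seed(7)
  m <- fm(c(runif(18), NA, pi / 7), 4, 5, "cg")
  m[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(m, path)
  m2 <- read_feature_matrix(path, "methylation", validate_range = FALSE)
  attr(m2, "kind") <- NULL
  expect_identical(m2, m)
})

test_that("align_samples intersects in first-input order and reports drops", {
  a <- fm(1:6 * 1.0, 2, 3, "a", samples = c("s1", "s2", "s3"))
  b <- fm(1:6 * 1.0, 2, 3, "b", samples = c("s3", "s1", "s2"))
  out <- align_samples(list(a, b))
  expect_identical(colnames(out[[1]]), c("s1", "s2", "s3"))
  expect_identical(colnames(out[[2]]), c("s1", "s2", "s3"))
  expect_identical(nrow(attr(out, "dropped")), 0L)

  c7 <- fm(1:14 * 1.0, 2, 7, "c",
           samples = paste0("s", 1:7))
  d5 <- fm(1:10 * 1.0, 2, 5, "d",
           samples = paste0("s", 3:7))
  out <- align_samples(list(c7, d5))
  expect_identical(colnames(out[[1]]), paste0("s", 3:7))
  expect_setequal(attr(out, "dropped")$sample_id, c("s1", "s2"))

  disjoint <- fm(1:4 * 1.0, 2, 2, "e", samples = c("x1", "x2"))
  expect_error(align_samples(list(a, disjoint)), "no shared samples")
})

test_that("align_samples is idempotent", {
  a <- fm(1:8 * 1.0, 2, 4, "a", samples = c("s2", "s4", "s1", "s3"))
  b <- fm(1:6 * 1.0, 2, 3, "b", samples = c("s1", "s3", "s2"))
  once <- align_samples(list(a, b))
  twice <- align_samples(once)
  expect_identical(lapply(twice, unclass), lapply(once, unclass))
})

test_that("BED4 annotations parse and validate", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t101\tcg0001", path)
  ann <- read_annotation(path)
  expect_identical(ann$feature_id, "cg0001")
  expect_identical(ann$chrom, "chr1")
  expect_identical(ann$start, 100L)
  expect_identical(ann$end, 101L)

  writeLines(c("chr1\t100\t101\tcg0001", "chr2\t5\t6\tcg0001"), path)
  expect_error(read_annotation(path), "duplicate")
  writeLines("chr1\t-5\t6\tcg0001", path)
  expect_error(read_annotation(path), "invalid interval")
  writeLines("chr1\t10\t6\tcg0001", path)
  expect_error(read_annotation(path), "invalid interval")
})

test_that("write_results emits the fixed column order and streams counts", {
  recs <- tibble::tibble(
    outcome_id = c("cg1", "cg2", "cg3"),
    predictor_id = c("rs1", "rs2", "rs3"),
    beta = c(0.5, -0.2, 0.1),
    t_stat = c(9.1, -4.2, 2.2),
    p_value = c(1e-8, 1e-4, 0.03),
    fdr = c(3e-8, 1.5e-4, 0.03))
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_identical(write_results(recs, path), 3L)
  lines <- readLines(path)
  expect_length(lines, 4L)
  expect_identical(lines[1],
                   "outcome_id\tpredictor_id\tbeta\tt_stat\tp_value\tfdr")

  expect_identical(write_results(recs[0, ], path), 0L)
  expect_length(readLines(path), 1L)

  expect_error(write_results(recs[c(3, 1, 2), ], path),
               "sorted by ascending p-value")
})

test_that("written results re-parse to 12 significant digits", {
  set.seed(11)
  p <- sort(runif(50))
  recs <- tibble::tibble(
    outcome_id = paste0("cg", 1:50), predictor_id = paste0("rs", 1:50),
    env_id = "env1", beta = rnorm(50), t_stat = rnorm(50) * 5,
    p_value = p, fdr = bh_fdr(p), pair_class = "cis")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(recs, path)
  back <- read_results(path)
  expect_identical(names(back),
                   c("outcome_id", "predictor_id", "env_id", "beta",
                     "t_stat", "p_value", "fdr", "pair_class"))
  for (cc in c("beta", "t_stat", "p_value")) {
    expect_equal(signif(back[[cc]], 12), signif(recs[[cc]], 12))
  }
})
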