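test_that("reading a feature table distinguishes censored cells and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tglucose\tlactate",
               "s1\t2.0\t3.5",
               "s2\t\t1.0",
               "s3\t4.0\t2.0"), path)
  ds <- read_dataset(path, batch_id = "b1")
  expect_s3_class(ds, "raw_dataset")
  expect_identical(dim(ds$values), c(3L, 2L))
  expect_true(ds$censored["s2", "glucose"])
  expect_identical(sum(ds$censored), 1L)
  expect_true(is.na(ds$values["s2", "glucose"]))

  # sentinel string also marks censoring
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tglucose", "s1\tNA", "s2\t1"), path2)
  expect_identical(sum(read_dataset(path2)$censored), 1L)

  # negative value rejected with location
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tglucose", "s1\t-1.0"), path3)
  expect_error(read_dataset(path3), "glucose")

  # duplicate feature header rejected
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tlactate\tlactate", "s1\t1\t2"), path4)
  expect_error(read_dataset(path4), "lactate")

  # non-numeric non-sentinel cell rejected
  path5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tglucose", "s1\tabc"), path5)
  expect_error(read_dataset(path5), "abc")
})

test_that("harmonization renames features, passes identity, and catches collisions", {
  ds <- raw_dataset(toy_matrix(1:6, 3, features = c("Lactic acid", "D-Glucose")))
  h <- harmonize(ds, c("Lactic acid" = "lactate"))
  expect_identical(colnames(h$values), c("lactate", "D-Glucose"))

  ident <- harmonize(ds, c("nothing" = "else"))
  expect_identical(colnames(ident$values), colnames(ds$values))
  expect_identical(ident$values, ds$values)

  expect_error(
    harmonize(ds, c("Lactic acid" = "glucose", "D-Glucose" = "glucose")),
    "collision")
  expect_error(harmonize(ds, c("Lactic acid" = "lactate"), unmapped = "error"),
               "D-Glucose")
})

test_that("aggregation stacks batches, preserves observed values and counts", {
  d1 <- rank_transform(raw_dataset(toy_matrix(c(1, 2, 3, 4), 2,
                                              features = c("a", "b")), "b1"))
  d2 <- rank_transform(raw_dataset(toy_matrix(c(5, 6, 7, 8), 2,
                                              samples = c("t1", "t2"),
                                              features = c("c", "d")), "b2"))
  agg <- quiet(aggregate_ranked(list(d1, d2)))
  expect_identical(dim(agg$values), c(4L, 4L))
  # block-diagonal observed mask for disjoint features
  expect_identical(unname(agg$observed),
                   rbind(c(TRUE, TRUE, FALSE, FALSE),
                         c(TRUE, TRUE, FALSE, FALSE),
                         c(FALSE, FALSE, TRUE, TRUE),
                         c(FALSE, FALSE, TRUE, TRUE)))
  # observed values preserved exactly
  expect_identical(agg$values[1:2, c("a", "b")], d1$values)
  expect_identical(agg$values[3:4, c("c", "d")], d2$values)
  # observed count = sum over batches of samples x measured features
  expect_identical(sum(agg$observed), 2L * 2L + 2L * 2L)

  # single batch aggregates to itself with an all-true mask
  agg1 <- quiet(aggregate_ranked(list(d1)))
  expect_identical(agg1$values, d1$values)
  expect_true(all(agg1$observed))

  # identical feature sets: fully observed
  d3 <- rank_transform(raw_dataset(toy_matrix(c(9, 1, 4, 6), 2,
                                              samples = c("u1", "u2"),
                                              features = c("a", "b")), "b3"))
  agg2 <- quiet(aggregate_ranked(list(d1, d3)))
  expect_true(all(agg2$observed))
})

test_that("duplicate sample ids across batches are namespaced, never merged", {
  d1 <- rank_transform(raw_dataset(toy_matrix(1:4, 2), "b1"))
  d2 <- rank_transform(raw_dataset(toy_matrix(5:8, 2), "b2"))
  agg <- quiet(aggregate_ranked(list(d1, d2)))
  expect_identical(rownames(agg$values), c("b1:s1", "b1:s2", "b2:s1", "b2:s2"))
  expect_identical(nrow(agg$values), 4L)
})

test_that("matrix write/read round-trips values, mask, and labels", {
  m <- toy_matrix(runif(9), 3)
  m[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_equal(back, m, tolerance = 1e-12)
  expect_identical(is.na(back), is.na(m))
  expect_identical(dimnames(back), dimnames(m))

  # empty matrix: header-only file, re-read gives zero samples
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("a", "b")))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(empty, path2)
  expect_identical(nrow(read_matrix(path2)), 0L)
})

test_that("dataset invariants reject malformed input", {
  expect_error(raw_dataset(toy_matrix(c(1, -2, 3, 4), 2)), "negative")
  expect_error(raw_dataset(toy_matrix(1:4, 2, samples = c("s1", "s1"))),
               "duplicate sample")
  expect_error(raw_dataset(matrix(1:4, 2)), "names")
})
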