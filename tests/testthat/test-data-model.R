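# Manifest I/O, fold bookkeeping and preprocessing.

test_that("manifest round-trips and parses toy label vectors", {
  df <- toy_records(3)
  df[1, -1] <- c(1, 1, 0, 0, 1, 0, 0)
  df[2, -1] <- rep(0, 7)
  df[3, -1] <- c(1, rep(0, 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(df, path)
  rec <- load_manifest(path)
  expect_equal(nrow(rec), 3)
  expect_equal(as.vector(label_matrix(rec)[1, ]), c(1, 1, 0, 0, 1, 0, 0))
  expect_equal(label_matrix(rec), label_matrix(df), ignore_attr = TRUE)
})

test_that("manifest validation rejects bad labels and unknown columns", {
  df <- toy_records(3)
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- df
  bad$osteolysis[2] <- 2
  utils::write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(load_manifest(path), "osteolysis.*'2'.*row 2")
  wrong <- df
  names(wrong)[3] <- "osteoLysis"
  utils::write.csv(wrong, path, row.names = FALSE, quote = FALSE)
  expect_error(load_manifest(path), "unknown column")
  # missing image files are reported when a root is supplied
  write_manifest(df, path)
  expect_warning(load_manifest(path, image_root = withr::local_tempdir()),
                 "missing")
})

test_that("a 443-row manifest yields 443 records", {
  set.seed(3)
  df <- toy_records(443)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(df, path)
  expect_equal(nrow(load_manifest(path)), 443)
})

test_that("fold plans cover every record once with near-equal sizes", {
  for (n in c(5, 17, 101, 200)) {
    for (k in c(2, 5)) {
      if (k > n) next
      plan <- make_folds(n, k, seed = n + k)
      expect_equal(sort(unique(plan$assignments)), seq_len(k))
      expect_equal(length(plan$assignments), n)
      sizes <- fold_sizes(plan)
      expect_lte(max(sizes) - min(sizes), 1)
      expect_equal(sum(sizes), n)
    }
  }
  expect_error(make_folds(3, 5), "exceeds")
})

test_that("fold assignment is seed-deterministic and seed-sensitive", {
  p1 <- make_folds(10, 5, seed = 1)
  p2 <- make_folds(10, 5, seed = 1)
  p3 <- make_folds(10, 5, seed = 2)
  expect_identical(p1$assignments, p2$assignments)
  expect_equal(fold_sizes(p1), fold_sizes(p3))
  expect_equal(fold_sizes(make_folds(5, 5, 1)), rep(1, 5))
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(p1, path)
  expect_identical(read_fold_plan(path)$assignments, p1$assignments)
})

test_that("6:2:2 split gives rounded proportions, disjoint and exhaustive", {
  s <- split_622(100, 1)
  expect_equal(lengths(s), c(train = 60, val = 20, test = 20))
  expect_equal(lengths(split_622(10, 1)), c(train = 6, val = 2, test = 2))
  set.seed(1)
  for (n in sample(5:200, 25)) {
    s <- split_622(n, seed = n)
    all_idx <- c(s$train, s$val, s$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0)
    expect_equal(length(s$train), floor(0.6 * n))
  }
  expect_identical(split_622(50, 9), split_622(50, 9))
})

test_that("preprocessing resizes, replicates grayscale and normalises", {
  set.seed(5)
  img <- matrix(runif(512 * 384), 512, 384)
  spec <- preprocess_spec(target_size = 224)
  out <- preprocess(img, spec)
  expect_equal(dim(out), c(224, 224, 3))
  # grayscale replicated to three identical channels before normalisation
  spec0 <- preprocess_spec(target_size = 64, mean = c(0, 0, 0), sd = c(1, 1, 1))
  out0 <- preprocess(img, spec0)
  expect_equal(out0[, , 1], out0[, , 2])
  expect_equal(out0[, , 2], out0[, , 3])
  # constant image with mean equal to that constant and unit sd -> zeros
  cimg <- matrix(0.37, 50, 60)
  outc <- preprocess(cimg, preprocess_spec(target_size = 32,
                                           mean = rep(0.37, 3),
                                           sd = rep(1, 3)))
  expect_equal(max(abs(outc)), 0)
  expect_error(preprocess("no/such/file.png"), "no/such/file.png")
})

test_that("preprocessing round-trips through PNG files", {
  set.seed(6)
  dir <- withr::local_tempdir()
  img <- matrix(runif(64 * 64), 64, 64)
  png::writePNG(img, file.path(dir, "a.png"))
  spec <- preprocess_spec(target_size = 64, mean = rep(0, 3), sd = rep(1, 3))
  out <- preprocess(file.path(dir, "a.png"), spec)
  expect_lt(max(abs(out[, , 1] - img)), 1 / 255)
})
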