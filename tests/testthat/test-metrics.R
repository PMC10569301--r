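# Evaluation metrics against brute-force oracles and closed-form identities.

test_that("average precision matches hand-enumerated examples", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               (1 / 2) * (1 / 1 + 2 / 3), tolerance = 1e-12)
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 1, 1)), 1)
  # all positives ranked above all negatives
  expect_equal(average_precision(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0)), 1)
  expect_error(average_precision(c(1, 2), c(0, 0)), "no positives")
})

test_that("average precision equals the rank-loop oracle on random data", {
  set.seed(70)
  for (i in 1:500) {
    n <- sample(5:25, 1)
    scores <- round(rnorm(n), 1)                  # coarse scores force ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    expect_equal(average_precision(scores, labels), brute_ap(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("mAP averages per-class APs and excludes empty classes", {
  scores <- cbind(c(0.9, 0.8, 0.7, 0.6), c(0.1, 0.9, 0.5, 0.3))
  labels <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 0))
  expect_equal(mean_average_precision(scores, labels),
               mean(c(5 / 6, 1)), tolerance = 1e-12)
  labels0 <- cbind(c(1, 0, 1, 0), rep(0, 4))
  expect_warning(m <- mean_average_precision(scores, labels0), "excluded")
  expect_equal(m, 5 / 6)
  set.seed(71)
  for (i in 1:20) {
    sc <- matrix(rnorm(40), 10, 4)
    lb <- matrix(rbinom(40, 1, 0.5), 10, 4)
    lb[1, ] <- 1
    m <- mean_average_precision(sc, lb)
    expect_gte(m, 0); expect_lte(m, 1)
  }
})

test_that("F1 arithmetic honours the harmonic-mean identities", {
  # P = R implies F1 = P exactly
  for (p in c(0.1, 0.5, 0.964)) expect_equal(f1_score(p, p), p)
  # harmonic <= arithmetic mean, F1 <= 2 min(P, R), over a grid
  grid <- expand.grid(p = seq(0.05, 1, by = 0.05), r = seq(0.05, 1, by = 0.05))
  f <- f1_score(grid$p, grid$r)
  expect_true(all(f <= (grid$p + grid$r) / 2 + 1e-12))
  expect_true(all(f <= 2 * pmin(grid$p, grid$r) + 1e-12))
  expect_equal(f1_score(0, 0), 0)
})

test_that("prf1 and accuracy follow the confusion-count definitions", {
  cnt <- c(tp = 3, tn = 5, fp = 1, fn = 1)
  pr <- prf1(cnt)
  expect_equal(pr[["precision"]], 3 / 4)
  expect_equal(pr[["recall"]], 3 / 4)
  expect_equal(accuracy(cnt), 0.8)
  expect_equal(accuracy(c(tp = 4, tn = 6, fp = 0, fn = 0)), 1)
  expect_warning(prf1(c(tp = 0, tn = 5, fp = 0, fn = 2)), "precision undefined")
  # polarity swap maps (tp, tn, fp, fn) -> (fn, fp, tn, tp): accuracy of the
  # complement predictor is 1 - accuracy on the same counts
  for (tp in 0:3) for (tn in 0:3) for (fp in 0:3) for (fn in 0:3) {
    if (tp + tn + fp + fn == 0) next
    a <- accuracy(c(tp = tp, tn = tn, fp = fp, fn = fn))
    b <- accuracy(c(tp = fn, tn = fp, fp = tn, fn = tp))
    expect_equal(a + b, 1)
  }
})

test_that("weighted metrics equal the explicit support-weighted oracle", {
  set.seed(72)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    sc <- matrix(rnorm(n * 5), n, 5)
    lb <- matrix(rbinom(n * 5, 1, 0.4), n, 5)
    lb[1, ] <- 1
    expect_equal(weighted_prf1(sc, lb), brute_weighted_prf1(sc, lb),
                 tolerance = 1e-9)
  }
  # equal supports reduce the weighted average to the macro average
  sc <- matrix(rnorm(40), 20, 2)
  lb <- cbind(rep(c(1, 0), 10), rep(c(0, 1), 10))
  w <- weighted_prf1(sc, lb)
  rep <- suppressWarnings(evaluate_predictions(sc, lb))
  expect_equal(unname(w), unname(rep$macro), tolerance = 1e-12)
  # single-class data: weighted equals that class's metrics
  sc1 <- matrix(rnorm(20), 20, 1)
  lb1 <- matrix(rbinom(20, 1, 0.6), 20, 1)
  expect_equal(weighted_prf1(sc1, lb1)[["f1"]],
               suppressWarnings(prf1(confusion_counts(
                 (plogis(sc1[, 1]) >= 0.5) * 1, lb1[, 1])))[["f1"]])
})

test_that("raising the decision threshold never increases recall", {
  set.seed(73)
  sc <- matrix(rnorm(200), 100, 2)
  lb <- matrix(rbinom(200, 1, 0.5), 100, 2)
  lb[1, ] <- 1
  recalls <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    weighted_prf1(sc, lb, threshold = th)[["recall"]]
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("evaluation reports serialise and carry per-class rows", {
  set.seed(74)
  sc <- matrix(rnorm(30 * 7), 30, 7)
  lb <- matrix(rbinom(30 * 7, 1, 0.4), 30, 7)
  lb[1, ] <- 1
  rep <- evaluate_predictions(sc, lb)
  expect_equal(rep$per_class$label, complication_labels())
  expect_equal(nrow(rep$per_class), 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$map, rep$map, tolerance = 1e-12)
})

test_that("the no-skill baseline tracks class prevalence", {
  set.seed(75)
  lb <- matrix(rbinom(50 * 3, 1, 0.3), 50, 3)
  lb[1, ] <- 1
  b <- noskill_map(lb, n_sim = 100, seed = 2)
  expect_gt(b, mean(colMeans(lb)) * 0.5)
  expect_lt(b, mean(colMeans(lb)) * 2)
  expect_identical(noskill_map(lb, 50, 3), noskill_map(lb, 50, 3))
})
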