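# sub-epoch counts per animal and class shaped like the modeled cohort
cohortShapedLabels <- function() {
  g0 <- c(0, 40, 0, 0, 44, 0, 2, 33)
  g1 <- c(15, 1, 28, 12, 1, 14, 35, 0)
  ids <- rep(sprintf("animal%d", 1:8), times = g0 + g1)
  y <- unlist(lapply(1:8, function(i) rep(c(0L, 1L), c(g0[i], g1[i]))))
  list(ids = ids, y = y)
}

test_that("leave-one-animal-out folds partition the cohort", {
  d <- cohortShapedLabels()
  folds <- makeLoaoFolds(d$ids, d$y)
  expect_length(folds, 8L)
  allTest <- sort(unlist(lapply(folds, `[[`, "testIdx")))
  expect_identical(allTest, seq_along(d$ids))
  for (f in folds) {
    expect_length(intersect(f$trainIdx, f$testIdx), 0L)
    expect_identical(sort(c(f$trainIdx, f$testIdx)), seq_along(d$ids))
  }
  expect_error(makeLoaoFolds(rep("only", 4), c(0, 1, 0, 1)), "at least 2")
  expect_error(makeLoaoFolds(c("a", "a", "b", "b"), c(0, 0, 1, 1)),
               "single class")
})

test_that("the fold holding out animal 7 trains on 117 group-0 / 71 group-1 sub-epochs", {
  d <- cohortShapedLabels()
  folds <- makeLoaoFolds(d$ids, d$y)
  f7 <- folds[[7]]
  expect_identical(sum(d$y[f7$trainIdx] == 0), 117L)
  expect_identical(sum(d$y[f7$trainIdx] == 1), 71L)
  aug <- smoteAugment(matrix(rnorm(188 * 3), 188, 3), d$y[f7$trainIdx],
                      seed = 1)
  expect_identical(as.vector(table(aug$y)), c(117L, 117L))
})

test_that("confusion matrices count as defined", {
  cm <- confusionMatrix01(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(c(cm@tp, cm@tn, cm@fp, cm@fn), c(2L, 2L, 0L, 0L))
  cm2 <- confusionMatrix01(c(1, 0), c(1, 1))
  expect_identical(c(cm2@tp, cm2@fp), c(1L, 1L))
  expect_error(confusionMatrix01(integer(0), integer(0)), "empty")
  expect_error(confusionMatrix01(c(1, 0), c(1)), "differ")
  expect_error(confusionMatrix01(c(1, 2), c(1, 0)), "0 or 1")
})

test_that("scalar metrics follow their definitions, with NA for empty denominators", {
  m <- classifierMetrics(new("ConfusionMatrix", tp = 8L, tn = 8L,
                             fp = 2L, fn = 2L))
  expect_equal(unname(m[c("accuracy", "sensitivity", "specificity",
                          "precision", "f1")]),
               rep(0.8, 5))
  perfect <- classifierMetrics(new("ConfusionMatrix", tp = 5L, tn = 5L,
                                   fp = 0L, fn = 0L))
  expect_true(all(perfect == 1))
  ws <- testthat::capture_warnings(
    bad <- classifierMetrics(new("ConfusionMatrix", tp = 0L, tn = 4L,
                                 fp = 0L, fn = 0L)))
  expect_match(ws, "undefined", all = TRUE)
  expect_length(ws, 2L)   # sensitivity and precision both undefined
  expect_true(is.na(bad[["sensitivity"]]))
  expect_true(is.na(bad[["precision"]]))
  expect_true(is.na(bad[["f1"]]))
  expect_equal(f1Score(0.906, 0.807), 0.8536, tolerance = 1e-4)
})

test_that("ROC/AUC agrees with exhaustive pair counting and Mann-Whitney U", {
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(rocAuc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_equal(rocAuc(c(1, 0, 1), c(0.9, 0.8, 0.7))$auc, 0.5)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "both classes")

  # trapezoid AUC == U / (n1 n0) on many random problems with ties
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- 20
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      sc <- round(runif(n), 1)
      u <- (sum(rank(sc)[y == 1]) - sum(y) * (sum(y) + 1) / 2) /
        (sum(y) * sum(1 - y))
      expect_equal(rocAuc(y, sc)$auc, u, tolerance = 1e-12)
    })
  }
  # cross-check against an independent ROC implementation
  withr::with_seed(99, {
    y <- rbinom(200, 1, 0.4)
    sc <- runif(200) + 0.4 * y
  })
  expect_equal(rocAuc(y, sc)$auc,
               suppressMessages(as.numeric(pROC::auc(y, sc))),
               tolerance = 1e-9)
})

test_that("pooled evaluation produces a coherent report on a synthetic cohort", {
  fs <- demoFeatureSet()
  rep1 <- evaluateAll(fs, seed = 1)
  met <- rep1@metrics
  expect_identical(rownames(met),
                   c("LR", "SVM", "KNN", "RF", "MLP", "mean"))
  # pooled confusion totals equal the cohort size for every model
  for (cm in rep1@confusion) {
    expect_identical(cm@tp + cm@tn + cm@fp + cm@fn, ncol(fs))
  }
  # F1 harmonic-mean identity on every model row
  for (r in 1:5) {
    expect_equal(met$f1[r], f1Score(met$precision[r], met$sensitivity[r]),
                 tolerance = 1e-9)
  }
  # mean row is the arithmetic mean of the five model rows
  expect_equal(unlist(met["mean", ]), colMeans(met[1:5, ]),
               tolerance = 1e-12)
  # determinism
  rep2 <- evaluateAll(fs, seed = 1)
  expect_identical(rep1@metrics, rep2@metrics)
  expect_error(evaluateAll(fs, features = "NotAFeature"), "unknown feature")
})
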