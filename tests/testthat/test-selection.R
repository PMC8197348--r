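test_that("pooled-variance t-test matches the closed form and its conventions", {
  # hand-computed 3-vs-3 case via the pooled-variance formula
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(0, 0, 0, 1, 1, 1)
  sp <- sqrt(((3 - 1) * 1 + (3 - 1) * 1) / 4)      # pooled sd = 1
  tStat <- (2 - 5) / (sp * sqrt(1 / 3 + 1 / 3))
  pOracle <- 2 * pt(tStat, df = 4)
  expect_equal(tStat, -3.674, tolerance = 1e-3)
  p <- ttestPvalues(X, y)
  expect_equal(unname(p), pOracle, tolerance = 1e-12)
  expect_equal(round(unname(p), 3), 0.021)

  # identical groups: t = 0, p = 1
  X2 <- matrix(rep(c(1, 2, 3), 2), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(unname(ttestPvalues(X2, y)), 1)

  # widely separated normals
  X3 <- matrix(c(withr::with_seed(1, rnorm(50)),
                 withr::with_seed(2, rnorm(50, 5))), ncol = 1,
               dimnames = list(NULL, "f"))
  expect_lt(ttestPvalues(X3, rep(0:1, each = 50))[1], 1e-6)

  # zero variance in both groups -> p = 1 with a warning
  X4 <- matrix(c(rep(1, 3), rep(1, 3)), ncol = 1,
               dimnames = list(NULL, "f"))
  expect_warning(p4 <- ttestPvalues(X4, y), "zero variance")
  expect_equal(unname(p4), 1)

  expect_error(ttestPvalues(X, rep(0, 6)), "per class")
})

test_that("t-test p-values are invariant to affine feature rescaling", {
  set.seed(10)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(0:1, 50)
  p1 <- ttestPvalues(X, y)
  X2 <- sweep(sweep(X, 2, c(3, 0.2), "*"), 2, c(-7, 100), "+")
  expect_equal(ttestPvalues(X2, y), p1, tolerance = 1e-9)
})

test_that("NCA ranks a separating feature first across seeded cohorts", {
  hits <- vapply(1:25, function(s) {
    withr::with_seed(s, {
      n <- 200
      y <- rep(0:1, each = n / 2)
      X <- cbind(sep = ifelse(y == 1, 2, -2) + rnorm(n, 0, 0.5),
                 matrix(rnorm(n * 5), n, 5,
                        dimnames = list(NULL, paste0("noise", 1:5))))
      ncaRank(X, y)$ranking[1] == "sep"
    })
  }, logical(1))
  expect_gte(sum(hits), 24)
})

test_that("NCA weights respect symmetry, the penalty limit and input checks", {
  set.seed(1)
  n <- 150
  y <- rep(0:1, each = 75)
  f <- ifelse(y == 1, 1.5, -1.5) + rnorm(n)
  X <- cbind(a = f, b = f, c = rnorm(n))
  w <- ncaRank(X, y)$weights
  expect_lt(abs(w[["a"]] - w[["b"]]), 0.1 * max(w))
  # feature permutation permutes the ranking accordingly
  r1 <- ncaRank(X, y)$ranking
  r2 <- ncaRank(X[, c("c", "b", "a")], y)$ranking
  expect_setequal(utils::head(r1, 2), utils::head(r2, 2))
  # very large penalty shrinks everything to zero
  wBig <- ncaRank(X, y, lambda = 100)$weights
  expect_lt(max(wBig), 1e-6)
  expect_error(ncaRank(X, rep(1, n)), "single-class")
})

test_that("selection keeps the top-ranked significant features and only those", {
  ref <- selectionReference()
  ranking <- ref$feature[order(ref$nca_rank)]
  pvals <- setNames(ref$p_upper, ref$feature)
  sel <- selectFeatures(ranking, pvals, K = 10)
  expect_identical(sel,
    c("BcSEF", "SpectralEntropy", "DeltaPR", "DeltaR", "DTABR", "DAR",
      "RenyiEntropy", "BG_Alpha_plus", "LogEnergyEntropy", "Magnitude"))
  expect_false("BetaR" %in% sel)   # rank 4 but p = 0.864
  expect_false("BSR" %in% sel)     # p < 0.001 but rank 18
  expect_identical(sort(sel),
                   sort(ref$feature[ref$result == "Selected"]))
  # nothing significant -> error
  expect_error(selectFeatures(ranking, setNames(rep(0.5, 20), ref$feature)),
               "significant")
})
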