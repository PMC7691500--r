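test_that("prediction loss matches hand-evaluated cross-entropy and MSE", {
  expect_equal(predictionLoss(c(1, 0), c(0.5, 0.5), "classification"),
               log(2), tolerance = 1e-12)
  expect_lt(predictionLoss(1, 1 - 1e-9, "classification"), 1e-6)
  expect_identical(predictionLoss(c(1, 2, 3), c(1, 2, 3), "regression"), 0)
  expect_error(predictionLoss(c(1, 0), c(0.5), "classification"), "length")
  expect_error(predictionLoss(1, 1.2, "classification"), "lie in")
})

test_that("squared correlation matches the Pearson formula and edge rules", {
  expect_equal(squaredCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(squaredCorrelation(c(1, 2, 3), c(3, 1, 2)), 0.25,
               tolerance = 1e-12)
  expect_identical(squaredCorrelation(c(1, 2, 3), c(2, 2, 2)), 0)
  expect_error(squaredCorrelation(1, 1), "length")
})

test_that("squared correlation is invariant to non-degenerate affine maps", {
  set.seed(31)
  for (i in 1:20) {
    u <- rnorm(50)
    v <- rnorm(50)
    a <- runif(1, -5, 5)
    b <- runif(1, 0.1, 4) * sample(c(-1, 1), 1)
    expect_equal(squaredCorrelation(u, a + b * v),
                 squaredCorrelation(u, v), tolerance = 1e-8)
  }
})

test_that("adversarial surrogate loss sums per-confounder correlations", {
  C <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))
  out <- confounderAdversarialLoss(C, C)
  expect_equal(out$L_cp, -2)
  expect_equal(unname(out$corr2), c(1, 1))
  constHat <- matrix(1, 4, 2)
  expect_equal(confounderAdversarialLoss(C, constHat)$L_cp, 0)
  expect_equal(confounderAdversarialLoss(matrix(c(1, 2, 3)),
                                         matrix(c(3, 1, 2)))$L_cp,
               -0.25, tolerance = 1e-12)
  expect_error(confounderAdversarialLoss(matrix(1), matrix(1)), "two")

  # bounds on random inputs
  set.seed(5)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    C <- matrix(rnorm(20 * k), ncol = k)
    H <- matrix(rnorm(20 * k), ncol = k)
    out <- confounderAdversarialLoss(C, H)
    expect_true(all(out$corr2 >= 0 & out$corr2 <= 1))
    expect_gte(out$L_cp, -k)
    expect_lte(out$L_cp, 0)
  }
})

test_that("objective combines losses with the trade-off weight", {
  expect_equal(objectiveValue(0.7, -1, 1), 1.7)
  expect_equal(objectiveValue(0.42, -0.9, 0), 0.42)
  expect_equal(objectiveValue(0.3, 0, 2), 0.3)
})

test_that("adversarial gradient matches finite differences", {
  corr2WithGrad <- cfnet:::corr2WithGrad
  set.seed(13)
  for (i in 1:5) {
    u <- rnorm(8)
    v <- rnorm(8)
    g <- corr2WithGrad(u, v)
    num <- vapply(seq_along(v), function(j) {
      e <- 1e-6
      vp <- v; vm <- v
      vp[j] <- vp[j] + e
      vm[j] <- vm[j] - e
      (corr2WithGrad(u, vp)$value - corr2WithGrad(u, vm)$value) / (2 * e)
    }, numeric(1))
    expect_equal(g$grad, num, tolerance = 1e-4)
  }
})

test_that("feature width follows the pooling and channel plan", {
  expect_equal(featureWidth(cfnetArchitecture(c(64L, 64L, 64L))), 4096L)
  expect_equal(featureWidth(cfnetArchitecture(c(32L, 32L))), 256L)
  # 32x32 with 4 stacks of size-2 pooling leaves a 2x2 spatial grid
  arch <- cfnetArchitecture(c(32L, 32L), nFiltersStart = 8L)
  expect_equal(featureWidth(arch), 2L * 2L * 32L)
  expect_error(cfnetArchitecture(c(30L, 30L)), "divisible")
})

test_that("model building is seed-deterministic with disjoint groups", {
  arch <- tinyArch(k = 2L)
  m1 <- buildModel(arch, "classification", seed = 9L)
  m2 <- buildModel(arch, "classification", seed = 9L)
  expect_identical(m1@thetaFE, m2@thetaFE)
  expect_identical(m1@thetaP, m2@thetaP)
  expect_identical(m1@thetaCP, m2@thetaCP)
  m3 <- buildModel(arch, "classification", seed = 10L)
  expect_false(identical(m1@thetaFE, m3@thetaFE))
  # detaching the confounder head does not shift the other groups
  m4 <- buildModel(arch, "classification", seed = 9L, includeCP = FALSE)
  expect_identical(m4@thetaFE, m1@thetaFE)
  expect_identical(m4@thetaP, m1@thetaP)
  expect_length(m4@thetaCP, 0L)
})

test_that("forward pass emits features, probabilities and k confounders", {
  arch <- tinyArch(k = 3L)
  m <- buildModel(arch, "classification", seed = 2L)
  set.seed(1)
  imgs <- replicate(5, array(rnorm(64), c(8, 8)), simplify = FALSE)
  p <- predictCFNet(m, imgs)
  expect_length(p, 5L)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predictCFNet(m, imgs))
  f <- extractFeatures(m, imgs)
  expect_equal(dim(f), c(5L, featureWidth(arch)))
  ch <- cfnet:::headForward(m@thetaCP, f)$out
  expect_equal(dim(ch), c(5L, 3L))
  expect_error(predictCFNet(m, array(0, c(4, 4))), "shape")
})
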