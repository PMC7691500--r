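test_that("the generator realises the requested outcome-confounder link", {
  for (alpha in c(0, 0.5)) {
    gen <- generateConfounded(generatorSpec(n = 2000L,
                                            imageShape = c(16L, 16L),
                                            ycAssociation = alpha,
                                            seed = 21L))
    y <- outcomes(gen$dataset)
    cv <- confounderValues(gen$dataset)[, 1L]
    expect_lt(abs(cor(y, cv) - alpha), 0.05)
    # c | y is (approximately) unit-variance normal
    expect_equal(sd(cv[y == 0]), sqrt(1 - alpha^2), tolerance = 0.08)
  }
})

test_that("region intensities follow the generative model", {
  spec <- generatorSpec(n = 2000L, imageShape = c(16L, 16L), seed = 31L)
  gen <- generateConfounded(spec)
  y <- outcomes(gen$dataset)
  mA <- vapply(gen$dataset@images,
               function(im) mean(im[gen$truth$maskA]), numeric(1))
  # E[mean over A] = mu_y * P(y = 1); noise se = noiseSd/sqrt(|A| n)
  se <- spec@noiseSd / sqrt(sum(spec@maskA) * spec@n) +
    spec@yEffect * sd(y) / sqrt(spec@n)
  expect_lt(abs(mean(mA) - spec@yEffect * mean(y)), 3 * se)

  # confounder region with cEffect = 0 is pure noise
  gen0 <- generateConfounded(generatorSpec(n = 500L,
                                           imageShape = c(16L, 16L),
                                           cEffect = 0, seed = 32L))
  bVals <- unlist(lapply(gen0$dataset@images,
                         function(im) im[gen0$truth$maskB]))
  expect_lt(abs(mean(bVals)), 3 / sqrt(length(bVals)))
  expect_equal(sd(bVals), 1, tolerance = 0.02)

  # the confounder signal has zero local mean (checkerboard modulation)
  genC <- generateConfounded(generatorSpec(n = 200L,
                                           imageShape = c(16L, 16L),
                                           cEffect = 20, seed = 33L))
  bMean <- vapply(genC$dataset@images,
                  function(im) mean(im[genC$truth$maskB]), numeric(1))
  expect_lt(sd(bMean), 2)  # despite the huge amplitude, means stay noise-level
})

test_that("generation is seed-deterministic", {
  s <- generatorSpec(n = 20L, imageShape = c(8L, 8L), seed = 12L)
  g1 <- generateConfounded(s)
  g2 <- generateConfounded(s)
  expect_identical(g1$dataset@images, g2$dataset@images)
  expect_identical(outcomes(g1$dataset), outcomes(g2$dataset))
  g3 <- generateConfounded(generatorSpec(n = 20L, imageShape = c(8L, 8L),
                                         seed = 13L))
  expect_false(identical(g1$dataset@images, g3$dataset@images))
})

test_that("invalid region masks are rejected", {
  shape <- c(8L, 8L)
  mask <- array(FALSE, shape)
  mask[1:2, 1:2] <- TRUE
  expect_error(generatorSpec(imageShape = shape, maskA = mask, maskB = mask),
               "disjoint")
  empty <- array(FALSE, shape)
  expect_error(generatorSpec(imageShape = shape, maskA = empty,
                             maskB = mask),
               "nonempty")
})

test_that("the regression generator shifts outcomes by group", {
  gen <- generateConfounded(generatorSpec(n = 3000L,
                                          imageShape = c(8L, 8L),
                                          task = "regression",
                                          ycAssociation = 0.5,
                                          yInterval = c(0, 10),
                                          seed = 14L))
  y <- outcomes(gen$dataset)
  cv <- confounderValues(gen$dataset)[, 1L]
  expect_setequal(unique(cv), c(0, 1))
  expect_equal(mean(y[cv == 1]) - mean(y[cv == 0]), 1, tolerance = 0.25)
  expect_gte(min(y), 0 - 0.5)
  expect_lte(max(y), 10 + 0.5)
})

test_that("the Bayes ceiling matches a Monte-Carlo optimal classifier", {
  spec <- generatorSpec(n = 10L, yEffect = 1, noiseSd = 4)
  expect_equal(oracleBayesAccuracy(spec), pnorm(0.5), tolerance = 1e-12)
  # simulate the optimal region-A classifier: threshold the region mean
  set.seed(99)
  nA <- sum(spec@maskA)
  yDraw <- rbinom(1e5, 1L, 0.5)
  regionMean <- spec@yEffect * yDraw + rnorm(1e5, sd = 4 / sqrt(nA))
  pred <- as.integer(regionMean > spec@yEffect / 2)
  sens <- mean(pred[yDraw == 1] == 1)
  spec0 <- mean(pred[yDraw == 0] == 0)
  expect_equal(oracleBayesAccuracy(spec), (sens + spec0) / 2,
               tolerance = 0.01)

  expect_equal(oracleBayesAccuracy(generatorSpec(yEffect = 0)), 0.5)
  expect_gt(oracleBayesAccuracy(generatorSpec(yEffect = 100)), 0.9999)
  expect_error(oracleBayesAccuracy(
    generatorSpec(task = "regression", imageShape = c(8L, 8L))),
    "classification")
})
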