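# Build a tiny conditioned dataset + matching batches for trainStep tests.
tinySetup <- function(seed = 1L, k = 1L, batch = 8L) {
  ds <- makeTinyDataset(24L, seed = seed, k = k)
  ds <- conditionBinary(ds, 0)
  arch <- tinyArch(k)
  model <- buildModel(arch, "classification", seed = seed)
  state <- initTrainState(model, seed = seed)
  set.seed(seed + 100L)
  iA <- sample(nSamples(ds), batch)
  iC <- sample(which(rhoFlags(ds) == 1L), batch, replace = TRUE)
  list(ds = ds, state = state,
       batchAll = list(x = ds@images[iA], y = outcomes(ds)[iA]),
       batchCond = list(x = ds@images[iC],
                        C = confounderValues(ds)[iC, , drop = FALSE]))
}

test_that("each sub-update freezes the other parameter groups", {
  s <- tinySetup()
  cfg <- trainingConfig(lambda = 1, batchSize = 8L, maxIterations = 1L)

  s1 <- trainStep(s$state, s$batchAll, s$batchCond, cfg, steps = 1L)
  expect_identical(s1@model@thetaCP, s$state@model@thetaCP)
  expect_false(identical(s1@model@thetaFE, s$state@model@thetaFE))
  expect_false(identical(s1@model@thetaP, s$state@model@thetaP))

  s2 <- trainStep(s$state, s$batchAll, s$batchCond, cfg, steps = 2L)
  expect_identical(s2@model@thetaFE, s$state@model@thetaFE)
  expect_identical(s2@model@thetaP, s$state@model@thetaP)
  expect_identical(s2@model@buffers, s$state@model@buffers)
  expect_false(identical(s2@model@thetaCP, s$state@model@thetaCP))

  s3 <- trainStep(s$state, s$batchAll, s$batchCond, cfg, steps = 3L)
  expect_identical(s3@model@thetaCP, s$state@model@thetaCP)
  expect_identical(s3@model@thetaP, s$state@model@thetaP)
  expect_false(identical(s3@model@thetaFE, s$state@model@thetaFE))
})

test_that("the freeze contract also holds with the adversary extensions", {
  s <- tinySetup(k = 2L)
  cfg <- trainingConfig(lambda = 1, batchSize = 8L, cpSteps = 3L,
                        cpExactOutput = TRUE, advSteps = 2L,
                        weightDecay = 1e-3)
  s2 <- trainStep(s$state, s$batchAll, s$batchCond, cfg, steps = 2L)
  expect_identical(s2@model@thetaFE, s$state@model@thetaFE)
  expect_identical(s2@model@thetaP, s$state@model@thetaP)
  s3 <- trainStep(s$state, s$batchAll, s$batchCond, cfg, steps = 3L)
  expect_identical(s3@model@thetaCP, s$state@model@thetaCP)
  expect_identical(s3@model@thetaP, s$state@model@thetaP)
})

test_that("a lambda = 0 run is bit-identical to a detached baseline", {
  ds <- conditionBinary(makeTinyDataset(24L), 0)
  arch <- tinyArch()
  cfg0 <- trainingConfig(lambda = 0, batchSize = 8L, maxIterations = 10L,
                         learningRate = 1e-3, seed = 5L)
  cfgD <- trainingConfig(lambda = 0, batchSize = 8L, maxIterations = 10L,
                         learningRate = 1e-3, seed = 5L, detachCP = TRUE)
  st0 <- fitCFNet(ds, cfg0, arch = arch)
  stD <- fitCFNet(ds, cfgD, arch = arch)
  expect_identical(st0@model@thetaFE, stD@model@thetaFE)
  expect_identical(st0@model@thetaP, stD@model@thetaP)
  expect_identical(st0@model@buffers, stD@model@buffers)
})

test_that("training is fully seed-deterministic", {
  ds <- conditionBinary(makeTinyDataset(24L), 0)
  cfg <- trainingConfig(lambda = 1, batchSize = 8L, maxIterations = 6L,
                        learningRate = 1e-3, seed = 11L)
  a <- fitCFNet(ds, cfg, arch = tinyArch())
  b <- fitCFNet(ds, cfg, arch = tinyArch())
  expect_identical(a@lossHistory, b@lossHistory)
  expect_identical(a@model@thetaFE, b@model@thetaFE)
  expect_identical(a@model@thetaCP, b@model@thetaCP)
})

test_that("the adversarial loss record stays within its bounds", {
  ds <- conditionBinary(makeTinyDataset(30L, k = 2L), 0)
  cfg <- trainingConfig(lambda = 1, batchSize = 8L, maxIterations = 8L,
                        learningRate = 1e-3, seed = 2L)
  st <- fitCFNet(ds, cfg, arch = tinyArch(k = 2L))
  h <- st@lossHistory
  expect_equal(nrow(h), 8L)
  expect_true(all(h$L_cp >= -2 & h$L_cp <= 0))
  expect_true(all(h$corr2_1 >= 0 & h$corr2_1 <= 1))
})

test_that("baseline training reduces the prediction loss on separable data", {
  # strong outcome signal, no confounder signal: plainly learnable
  gen <- generateConfounded(generatorSpec(n = 200L,
                                          imageShape = c(16L, 16L),
                                          yEffect = 4, cEffect = 0,
                                          ycAssociation = 0, seed = 8L))
  cfg <- trainingConfig(lambda = 0, batchSize = 32L, maxIterations = 150L,
                        learningRate = 1e-3, seed = 8L, detachCP = TRUE)
  arch <- cfnetArchitecture(c(16L, 16L), nFiltersStart = 4L)
  st <- fitCFNet(gen$dataset, cfg, arch = arch)
  lp <- st@lossHistory$L_p
  expect_lt(mean(tail(lp, 10)), 0.5 * mean(head(lp, 5)))
})

test_that("training requires a conditioned cohort when the head is attached", {
  ds <- makeTinyDataset(20L)  # no rho flags set
  cfg <- trainingConfig(lambda = 1, batchSize = 8L, maxIterations = 2L)
  expect_error(fitCFNet(ds, cfg, arch = tinyArch()), "rho")
})

test_that("prediction is order-preserving over batches", {
  m <- buildModel(tinyArch(), "classification", seed = 3L)
  set.seed(4)
  imgs <- replicate(7, array(rnorm(64), c(8, 8)), simplify = FALSE)
  batch <- predictCFNet(m, imgs)
  single <- vapply(imgs, function(im) predictCFNet(m, im), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("augmentation preserves labels, shape and identity bounds", {
  img <- array(rnorm(64), c(8, 8))
  set.seed(1)
  expect_identical(augmentImage(img, maxShift = 0, maxRotationDeg = 0), img)

  s <- new("Sample", id = "a", image = img, y = 1, c = 2, rho = 1L)
  set.seed(2)
  out <- augmentSample(s, maxShift = 1, maxRotationDeg = 0)
  expect_identical(out@y, s@y)
  expect_identical(out@c, s@c)
  expect_identical(out@rho, s@rho)
  expect_identical(dim(out@image), dim(img))
})

test_that("integer shifts translate an impulse by the stated offset", {
  shiftImage <- cfnet:::shiftImage
  img <- array(0, c(8, 8))
  img[4, 5] <- 1
  out <- shiftImage(img, c(1L, 0L))
  expect_equal(which(out == 1, arr.ind = TRUE)[1, ], c(row = 5, col = 5))
  out2 <- shiftImage(img, c(0L, -2L))
  expect_equal(which(out2 == 1, arr.ind = TRUE)[1, ], c(row = 4, col = 3))
  # content shifted off the edge is dropped, zero fill
  expect_equal(sum(shiftImage(img, c(8L, 0L))), 0)
})

test_that("small rotations preserve the intensity of a smooth blob", {
  g <- outer(1:16, 1:16, function(i, j)
    exp(-((i - 8.5)^2 + (j - 8.5)^2) / 8))
  rot <- cfnet:::rotateImage(g, 1)
  expect_equal(sum(rot), sum(g), tolerance = 0.01)
  g3 <- array(0, c(12, 12, 12))
  for (k in 1:12)
    g3[, , k] <- outer(1:12, 1:12, function(i, j)
      exp(-((i - 6.5)^2 + (j - 6.5)^2 + (k - 6.5)^2) / 6))
  rot3 <- cfnet:::rotateImage(g3, c(1, 0.5, -1))
  expect_equal(sum(rot3), sum(g3), tolerance = 0.01)
})
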