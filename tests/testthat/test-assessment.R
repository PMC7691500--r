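test_that("classification metrics match hand confusion-matrix arithmetic", {
  # TP = 3, FN = 1, TN = 4, FP = 2
  yTrue <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  yProb <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.7, 0.1, 0.2, 0.3, 0.4)
  m <- classificationMetrics(yTrue, yProb)
  expect_equal(m[["bacc"]], (0.75 + 4 / 6) / 2, tolerance = 1e-12)
  expect_equal(m[["precision"]], 0.6)
  expect_equal(m[["recall"]], 0.75)
  expect_equal(m[["f1"]], 2 * 0.6 * 0.75 / 1.35, tolerance = 1e-12)

  perfect <- classificationMetrics(c(0, 1, 1), c(0.1, 0.9, 0.8))
  expect_equal(unname(perfect), rep(1, 4))

  allNeg <- classificationMetrics(c(0, 1, 0, 1), rep(0.2, 4))
  expect_equal(allNeg[["recall"]], 0)
  expect_equal(allNeg[["precision"]], 0)
  expect_equal(allNeg[["bacc"]], 0.5)
  expect_equal(allNeg[["f1"]], 0)

  expect_error(classificationMetrics(c(1, 1), c(0.2, 0.9)), "both classes")
})

test_that("metrics agree with a brute-force oracle on random labelings", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    yTrue <- c(0, 1, sample(0:1, n - 2L, replace = TRUE))
    yProb <- runif(n)
    m <- classificationMetrics(yTrue, yProb)
    pred <- ifelse(yProb >= 0.5, 1, 0)
    tp <- sum(pred & yTrue); fp <- sum(pred & !yTrue)
    fn <- sum(!pred & yTrue); tn <- sum(!pred & !yTrue)
    expect_equal(m[["bacc"]],
                 (tp / (tp + fn) + tn / (tn + fp)) / 2, tolerance = 1e-12)
    expect_equal(m[["recall"]], tp / (tp + fn), tolerance = 1e-12)
    expect_equal(m[["precision"]], if (tp + fp == 0) 0 else tp / (tp + fp),
                 tolerance = 1e-12)
  }
})

test_that("stratified evaluation reports per-stratum metrics and the gap", {
  yTrue <- rep(c(0, 1), 20)
  yProb <- ifelse(yTrue == 1, 0.9, 0.1)
  strata <- rep(c("low", "high"), each = 20)
  out <- stratifiedEval(yTrue, yProb, strata)
  expect_equal(nrow(out$perStratum), 2L)
  expect_equal(out$baccGap, 0)
  expect_setequal(out$perStratum$stratum, c("low", "high"))

  # constructed recall difference: gap computed on balanced accuracy
  yT <- c(rep(1, 50), rep(0, 50), rep(1, 50), rep(0, 50))
  yP <- c(rep(0.9, 18), rep(0.1, 32), rep(0.1, 50),   # recall 0.36
          rep(0.9, 33), rep(0.1, 17), rep(0.1, 50))   # recall 0.66
  st <- c(rep("a", 100), rep("b", 100))
  out2 <- stratifiedEval(yT, yP, st)
  ps <- out2$perStratum
  expect_equal(ps$recall[ps$stratum == "a"], 0.36)
  expect_equal(ps$recall[ps$stratum == "b"], 0.66)
  expect_equal(out2$baccGap, abs(0.68 - 0.83), tolerance = 1e-12)

  # a single-class stratum is reported with undefined balanced accuracy
  out3 <- stratifiedEval(c(1, 1, 0, 1), c(0.9, 0.2, 0.1, 0.8),
                         c("x", "x", "y", "y"))
  expect_true(is.na(out3$perStratum$bacc[out3$perStratum$stratum == "x"]))
})

test_that("the probe recovers a confounder stored verbatim in the features", {
  set.seed(6)
  n <- 200L
  cvals <- rnorm(n)
  feats <- cbind(cvals, matrix(rnorm(n * 4L), ncol = 4L))
  pr <- posthocProbe(feats, cvals, trainIds = 1:120, testIds = 121:200,
                     seed = 3L)
  expect_gte(pr$r, 0.99)
  expect_lt(pr$p, 1e-6)
})

test_that("the probe rejects overlapping splits and constant confounders", {
  feats <- matrix(rnorm(100), ncol = 2L)
  expect_error(posthocProbe(feats, rnorm(50), 1:30, 25:50, seed = 1L),
               "disjoint")
  expect_error(posthocProbe(feats, rep(1, 50), 1:30, 31:50, seed = 1L),
               "constant")
})

test_that("distance correlation equals an independent double-loop oracle", {
  dcorOracle <- function(X, y) {
    n <- nrow(X)
    A <- matrix(0, n, n)
    B <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      A[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
      B[i, j] <- abs(y[i] - y[j])
    }
    center <- function(D) {
      out <- D
      for (i in 1:n) for (j in 1:n)
        out[i, j] <- D[i, j] - mean(D[i, ]) - mean(D[, j]) + mean(D)
      out
    }
    A <- center(A)
    B <- center(B)
    dcov2 <- mean(A * B)
    sqrt(dcov2 / sqrt(mean(A * A) * mean(B * B)))
  }
  set.seed(77)
  X <- matrix(rnorm(100), 20L, 5L)
  y <- rnorm(20)
  expect_equal(distanceCorrelation(X, y), dcorOracle(X, y),
               tolerance = 1e-10)
})

test_that("distance correlation obeys its invariances", {
  set.seed(15)
  x <- rnorm(30)
  expect_equal(distanceCorrelation(x, x), 1, tolerance = 1e-10)
  expect_equal(distanceCorrelation(2 * x - 7, x), 1, tolerance = 1e-10)
  expect_identical(distanceCorrelation(rep(1, 30), x), 0)
  X <- matrix(rnorm(60), ncol = 2L)
  y <- rnorm(30)
  perm <- sample(30)
  expect_equal(distanceCorrelation(X, y),
               distanceCorrelation(X[perm, , drop = FALSE], y[perm]),
               tolerance = 1e-10)
  expect_error(distanceCorrelation(matrix(rnorm(6), 3L), rnorm(3)), "4")
})

test_that("mutual information distinguishes dependence from independence", {
  set.seed(9)
  x <- rnorm(600)
  yInd <- rnorm(600)
  expect_lt(mutualInformation(x, yInd), 0.1)
  rho <- 0.9
  yDep <- rho * x + sqrt(1 - rho^2) * rnorm(600)
  miDep <- mutualInformation(x, yDep)
  expect_gt(miDep, 0.5)
  # duplicated feature columns do not lose information
  miDup <- mutualInformation(cbind(x, x), yDep)
  expect_gte(miDup, miDep - 0.05)
  expect_error(mutualInformation(rnorm(10), rnorm(10)), "20")
})

test_that("bootstrap dependence replicates are seed-reproducible and usable", {
  set.seed(3)
  x <- rnorm(80)
  feats <- cbind(x + rnorm(80, sd = 0.3), rnorm(80))
  indep <- matrix(rnorm(160), ncol = 2L)
  b1 <- bootstrapDependence(feats, x, nBoot = 20L, seed = 4L)
  b2 <- bootstrapDependence(feats, x, nBoot = 20L, seed = 4L)
  expect_identical(b1$dcor, b2$dcor)
  expect_length(b1$mi, 20L)
  b0 <- bootstrapDependence(indep, x, nBoot = 20L, seed = 4L)
  cmp <- compareDependence(b1, b0)
  expect_true(all(cmp$meanDiff > 0))
  expect_true(all(cmp$p < 0.01))
})

test_that("saliency is zero for a zeroed head and concentrates at the argmax", {
  arch <- cfnetArchitecture(c(8L, 8L), nStacks = 2L, nFiltersStart = 4L,
                            headHiddenWidth = 4L)
  m <- buildModel(arch, "classification", seed = 1L)
  img <- array(abs(rnorm(64)), c(8, 8))
  mZero <- m
  mZero@thetaP$W1[] <- 0
  mZero@thetaP$W2[] <- 0
  expect_true(all(saliencyMap(mZero, img) == 0))

  # identity-like extractor: first conv channel copies the input pixel,
  # ReLU passes positives, both pools propagate the window maximum, and the
  # head reads that channel; the gradient lands on the maximal pixel.
  mId <- m
  for (s in 1:2) {
    W <- mId@thetaFE[[paste0("conv", s, ".W")]] * 0
    W[1L, 1L] <- 1   # offset (0,0), input channel 1 -> output channel 1
    mId@thetaFE[[paste0("conv", s, ".W")]] <- W
    mId@thetaFE[[paste0("conv", s, ".b")]][] <- 0
    mId@thetaFE[[paste0("bn", s, ".gamma")]][] <- 1
    mId@thetaFE[[paste0("bn", s, ".beta")]][] <- 0
    mId@buffers[[paste0("bn", s, ".mean")]][] <- 0
    mId@buffers[[paste0("bn", s, ".var")]][] <- 1
  }
  mId@thetaP$W1[] <- 0
  mId@thetaP$W1[1L, 1L] <- 1  # feature 1 = channel 1, spatial cell (1,1)
  mId@thetaP$b1[] <- 0
  mId@thetaP$W2[] <- 0
  mId@thetaP$W2[1L, 1L] <- 1
  sal <- saliencyMap(mId, img)
  peak <- which(sal == max(sal), arr.ind = TRUE)
  # the pooling path selects the maximum of the upper-left 4x4 block
  block <- img[1:4, 1:4]
  expect_equal(unname(peak[1, ]),
               unname(which(block == max(block), arr.ind = TRUE)[1, ]))
  expect_true(all(sal >= 0))
  expect_identical(dim(sal), dim(img))
})

test_that("assessModel assembles a complete report", {
  gen <- generateConfounded(generatorSpec(n = 80L, imageShape = c(16L, 16L),
                                          seed = 3L))
  test <- generateConfounded(generatorSpec(n = 60L, imageShape = c(16L, 16L),
                                           seed = 4L))
  arch <- cfnetArchitecture(c(16L, 16L), nFiltersStart = 4L)
  ds <- conditionBinary(gen$dataset, 0)
  st <- fitCFNet(ds, trainingConfig(lambda = 0, batchSize = 16L,
                                    maxIterations = 5L, detachCP = TRUE,
                                    seed = 1L), arch = arch)
  rep <- assessModel(st@model, test$dataset, trainDataset = ds,
                     probeSteps = 100L)
  expect_s4_class(rep, "AssessmentReport")
  expect_true(rep@bacc >= 0 && rep@bacc <= 1)
  expect_equal(nrow(rep@perStratum), 2L)
  expect_false(is.na(rep@dcor))
  expect_false(is.na(rep@posthocR))
  lst <- reportAsList(rep)
  expect_true(all(c("bacc", "precision", "recall", "f1", "dcor", "mi",
                    "posthoc_r") %in% names(lst)))
})
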