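test_that("binary conditioning flags exactly the chosen outcome group", {
  ds <- makeTinyDataset(20L)
  cond <- conditionBinary(ds, 0)
  expect_identical(rhoFlags(cond), as.integer(outcomes(ds) == 0))
  cond1 <- conditionBinary(ds, 1)
  expect_equal(sum(rhoFlags(cond1)), sum(outcomes(ds) == 1))

  allZero <- ds
  allZero@meta$y <- rep(0, 20L)
  expect_error(conditionBinary(allZero, 1), "no samples")
  expect_error(conditionBinary(makeTinyDataset(4L, task = "regression"), 0),
               "classification")
})

test_that("fwhm interval of a normal sample matches the closed form", {
  set.seed(42)
  x <- rnorm(1e5, mean = 100, sd = 40)
  iv <- fwhmInterval(x, binWidth = 2)
  expect_equal(diff(iv), 2 * sqrt(2 * log(2)) * 40, tolerance = 0.05)
  expect_equal(mean(iv), 100, tolerance = 0.05)
})

test_that("fwhm interval brackets only bins above half the dominant peak", {
  set.seed(7)
  x <- c(rnorm(2000, 0, 1), rnorm(150, 10, 0.5))
  iv <- fwhmInterval(x, binWidth = 0.25)
  expect_lt(iv[2L], 5)   # minor mode at 10 is below half maximum
  expect_gt(iv[1L], -4)
  expect_error(fwhmInterval(rep(1, 10)), "distinct")
})

test_that("greedy matching reproduces the hand-simulated pairing", {
  imgs <- replicate(6, array(0, c(2L, 2L)), simplify = FALSE)
  ds <- ConfoundedDataset(imgs, y = c(0, 0, 0, 0, 1, 1),
                          confounders = c(40, 50, 60, 70, 51, 62),
                          ids = sprintf("s%02d", 1:6))
  m <- greedyMatch(ds, pStop = 1e-9)
  expect_setequal(m@idsGroup1, c("s05", "s06"))
  expect_setequal(m@idsGroup0, c("s02", "s03"))  # ages 50 and 60
  expect_length(m@idsGroup0, length(m@idsGroup1))
})

test_that("greedy matching is invariant to input order and breaks ties by id", {
  set.seed(11)
  n <- 40L
  imgs <- replicate(n, array(0, c(2L, 2L)), simplify = FALSE)
  y <- rep_len(c(0, 0, 1), n)
  age <- round(rnorm(n, 50, 10))
  ds <- ConfoundedDataset(imgs, y, age, ids = sprintf("s%02d", seq_len(n)))
  m1 <- greedyMatch(ds)
  perm <- sample(n)
  m2 <- greedyMatch(ds[perm])
  expect_setequal(c(m1@idsGroup0, m1@idsGroup1),
                  c(m2@idsGroup0, m2@idsGroup1))

  # two majority candidates at the same distance: the smaller id wins
  ds2 <- ConfoundedDataset(replicate(3, array(0, c(2L, 2L)),
                                     simplify = FALSE),
                           y = c(0, 0, 1), confounders = c(49, 51, 50),
                           ids = c("a", "b", "z"))
  m3 <- greedyMatch(ds2, pStop = 1e-9)
  expect_identical(m3@idsGroup0, "a")
})

test_that("identical confounder distributions match the full minority group", {
  imgs <- replicate(8, array(0, c(2L, 2L)), simplify = FALSE)
  ds <- ConfoundedDataset(imgs, y = c(0, 0, 0, 0, 0, 1, 1, 1),
                          confounders = c(40, 50, 60, 45, 55, 40, 50, 60))
  m <- greedyMatch(ds)
  expect_length(m@idsGroup1, 3L)
  expect_equal(m@balancePValue, 1)
})

test_that("bootstrap matching draws the exact cell counts and sets weights", {
  ds <- makeMatchingDataset(400L, shift = 3)
  rule <- continuousConditioning(interval = c(75, 175), perBinCount = 50L,
                                 binWidth = 10, matchVariable = "sex")
  out <- bootstrapMatchedCohort(ds, rule, seed = 5L)
  expect_length(out$ids, 50L * 10L * 2L)  # perBin x bins x levels
  expect_identical(sum(out$dataset@meta$rho > 0L),
                   length(unique(out$ids)))
  # weights record the draw multiplicity
  drawn <- table(out$ids)
  w <- sampleWeights(out$dataset)[match(names(drawn), sampleIds(ds))]
  expect_equal(unname(w), as.numeric(drawn))
  expect_error(
    bootstrapMatchedCohort(makeMatchingDataset(10L), rule, seed = 1L),
    "empty cell")
})

test_that("bootstrap matching equalises the outcome distributions", {
  ds <- makeMatchingDataset(400L, shift = 8)
  rule <- continuousConditioning(interval = c(75, 175), perBinCount = 100L,
                                 binWidth = 10, matchVariable = "sex")
  # strongly shifted input distributions; the matched multiset passes a
  # two-sample t-test in almost every resampling
  pvals <- vapply(1:30, function(s)
    bootstrapMatchedCohort(ds, rule, seed = s)$balanceP, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.95)
})

test_that("bootstrap cohort approximates the within-interval distribution", {
  ds <- makeMatchingDataset(500L, shift = 2, seed = 3L)
  rule <- continuousConditioning(interval = c(75, 175),
                                 perBinCount = 1000L, binWidth = 10,
                                 matchVariable = "sex")
  out <- bootstrapMatchedCohort(ds, rule, seed = 9L)
  y <- outcomes(ds)
  sex <- ds@extra$sex
  idx <- match(out$ids, sampleIds(ds))
  for (lv in c(0, 1)) {
    drawn <- y[idx][sex[idx] == lv]
    pop <- y[sex == lv & y >= 75 & y <= 175]
    ks <- suppressWarnings(ks.test(drawn, pop))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("z-scoring uses the population convention and reference rows only", {
  imgs <- replicate(4, array(0, c(2L, 2L)), simplify = FALSE)
  ds <- ConfoundedDataset(imgs, c(0, 1, 0, 1), c(1, 2, 3, 2))
  zs <- zscoreConfounders(ds, referenceIds = c("s1", "s2", "s3"))
  expect_equal(unname(confounderValues(zs$dataset)[1:3, 1L]),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(zs$center, 2, ignore_attr = TRUE)
  expect_equal(zs$scale, sqrt(2 / 3), ignore_attr = TRUE)
  # held-out sample equal to the reference mean maps to 0
  expect_equal(unname(confounderValues(zs$dataset)[4L, 1L]), 0)
})

test_that("z-scoring inverts to the original values", {
  ds <- makeTinyDataset(30L, k = 3L, seed = 4L)
  orig <- confounderValues(ds)
  zs <- zscoreConfounders(ds)
  back <- sweep(sweep(confounderValues(zs$dataset), 2L, zs$scale, "*"),
                2L, zs$center, "+")
  expect_equal(back, orig, tolerance = 1e-10)

  const <- ds
  const@confounders[, 2L] <- 5
  expect_error(zscoreConfounders(const), "constant")
})
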