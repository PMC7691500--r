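#' Specify a synthetic confounded-image study
#'
#' The generator realises the canonical confounding diagram with known
#' ground truth: the confounder c influences both the image (through region
#' B) and, via its association with the outcome, the label; the outcome y
#' writes into a disjoint region A. For classification,
#' `y ~ Bernoulli(0.5)`, `c = alpha (2y - 1) + sqrt(1 - alpha^2) e` with
#' standard-normal `e` (so `corr(y, c) ~ alpha` and `c | y` has unit
#' variance), and `X = mu_y y 1_A + mu_c c P_B + noise`, where `P_B` is a
#' +/-1 checkerboard over region B. For regression, `c ~ Bernoulli(0.5)` is
#' a binary group, `y = Uniform(yInterval) + alpha (2c - 1)`, and the image
#' is formed the same way.
#'
#' The two signals are deliberately given different local textures — a
#' uniform shift for the outcome, a zero-local-mean checkerboard for the
#' confounder — mirroring the fact that outcome and confounder signatures
#' in real images are locally distinguishable patterns. (If both were
#' uniform shifts differing only in position, convolutional weight sharing
#' would force any feature extractor to carry both or neither, and
#' confounder-free features with retained accuracy would be unattainable
#' by construction.)
#'
#' Defaults describe a desk-scale study: 32 x 32 images, n = 1000,
#' 16-pixel regions, unit noise, a strong confounder signal (`cEffect` = 6)
#' over a weaker outcome signal (`yEffect` = 1.5), and intrinsic
#' association `alpha = 0.5`. At these settings a plainly trained network
#' learns the outcome region only partially within a few hundred
#' iterations and leans on the louder confounder region, so its accuracy
#' drops when the outcome-confounder association is switched off — the
#' confounded-baseline phenomenon the deconfounding study is built to
#' exhibit.
#'
#' @param n number of samples.
#' @param imageShape integer vector, length 2 or 3.
#' @param task `"classification"` or `"regression"`.
#' @param yEffect outcome signal amplitude mu_y.
#' @param cEffect confounder signal amplitude mu_c.
#' @param ycAssociation intrinsic association alpha in `[-1, 1]`.
#' @param noiseSd pixel noise standard deviation.
#' @param maskA,maskB disjoint logical region masks; defaults are two
#'   4 x 4 (x 1) blocks in opposite image corners.
#' @param yInterval outcome range for regression.
#' @param seed integer seed.
#' @return a [GeneratorSpec].
#' @export
generatorSpec <- function(n = 1000L, imageShape = c(32L, 32L),
                          task = c("classification", "regression"),
                          yEffect = 1.5, cEffect = 6,
                          ycAssociation = 0.5, noiseSd = 1,
                          maskA = NULL, maskB = NULL,
                          yInterval = c(0, 10), seed = 1L) {
  task <- match.arg(task)
  imageShape <- as.integer(imageShape)
  if (is.null(maskA) || is.null(maskB)) {
    m <- defaultMasks(imageShape)
    if (is.null(maskA)) maskA <- m$A
    if (is.null(maskB)) maskB <- m$B
  }
  new("GeneratorSpec", n = as.integer(n), imageShape = imageShape,
      task = task, yEffect = yEffect, cEffect = cEffect,
      ycAssociation = ycAssociation, noiseSd = noiseSd,
      maskA = maskA, maskB = maskB, yInterval = as.numeric(yInterval),
      seed = as.integer(seed))
}

# Two disjoint corner blocks of edge ~shape/8 (at least 2), e.g. 4 x 4
# blocks for a 32 x 32 image.
defaultMasks <- function(shape) {
  edge <- pmax(2L, shape %/% 8L)
  A <- array(FALSE, shape)
  B <- array(FALSE, shape)
  idxA <- lapply(seq_along(shape), function(a) seq_len(edge[a]) + edge[a])
  idxB <- lapply(seq_along(shape),
                 function(a) shape[a] - 2L * edge[a] + seq_len(edge[a]))
  A[as.matrix(expand.grid(idxA))] <- TRUE
  B[as.matrix(expand.grid(idxB))] <- TRUE
  list(A = A, B = B)
}

#' Generate a synthetic confounded dataset
#'
#' @param spec a [GeneratorSpec] (see [generatorSpec()] for the generative
#'   model).
#' @return list with `dataset` (a [ConfoundedDataset]) and `truth` (the
#'   masks and parameters, for downstream verification).
#' @examples
#' gen <- generateConfounded(generatorSpec(n = 50, imageShape = c(16, 16)))
#' nSamples(gen$dataset)
#' @export
generateConfounded <- function(spec) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  n <- spec@n
  shape <- spec@imageShape
  alpha <- spec@ycAssociation
  withRNG(spec@seed, {
    if (spec@task == "classification") {
      y <- stats::rbinom(n, 1L, 0.5)
      cvals <- alpha * (2 * y - 1) +
        sqrt(1 - alpha^2) * stats::rnorm(n)
    } else {
      cvals <- stats::rbinom(n, 1L, 0.5)
      y <- stats::runif(n, spec@yInterval[1L], spec@yInterval[2L]) +
        alpha * (2 * cvals - 1)
    }
    images <- vector("list", n)
    nvox <- prod(shape)
    patB <- checkerboard(shape)[spec@maskB]
    for (i in seq_len(n)) {
      img <- array(stats::rnorm(nvox, sd = spec@noiseSd), shape)
      img[spec@maskA] <- img[spec@maskA] + spec@yEffect * y[i]
      img[spec@maskB] <- img[spec@maskB] + spec@cEffect * cvals[i] * patB
      images[[i]] <- img
    }
    dataset <- ConfoundedDataset(images, y, matrix(cvals, ncol = 1L),
                                 task = spec@task)
    list(dataset = dataset,
         truth = list(maskA = spec@maskA, maskB = spec@maskB,
                      patternB = checkerboard(shape),
                      yEffect = spec@yEffect, cEffect = spec@cEffect,
                      ycAssociation = alpha, noiseSd = spec@noiseSd,
                      c = cvals))
  })
}

#' Bayes-optimal balanced accuracy from the outcome region alone
#'
#' The confounder-free accuracy ceiling of the synthetic classification
#' task: a Bayes classifier reading only region A sees the mean of |A|
#' pixels whose signal differs by `mu_y` between classes with noise
#' `noiseSd / sqrt(|A|)`, giving balanced accuracy
#' `Phi(mu_y sqrt(|A|) / (2 noiseSd))`. A trained model with higher test
#' accuracy on a confounded test set than this ceiling must be exploiting
#' the confounder region.
#'
#' @param spec a classification [GeneratorSpec].
#' @return a number in `[0.5, 1]`.
#' @export
oracleBayesAccuracy <- function(spec) {
  stopifnot(is(spec, "GeneratorSpec"))
  if (spec@task != "classification")
    stop("the accuracy ceiling is defined for classification specs")
  stats::pnorm(spec@yEffect * sqrt(sum(spec@maskA)) / (2 * spec@noiseSd))
}

# +/-1 parity checkerboard over the whole image; the confounder signal is
# modulated by it so its local mean vanishes.
checkerboard <- function(shape) {
  idx <- arrayInd(seq_len(prod(shape)), shape)
  array((-1)^rowSums(idx), shape)
}
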