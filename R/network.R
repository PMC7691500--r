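#' Describe the network architecture
#'
#' @param inputShape integer image shape, length 2 or 3; each dimension must
#'   be divisible by `poolSize^nStacks`.
#' @param nStacks number of convolution / ReLU / batch-norm / max-pool
#'   stacks.
#' @param kernelSize,poolSize kernel edge and pooling factor.
#' @param nFiltersStart channels of the first stack; the plan doubles for
#'   three stacks then stays flat, so `c(64, 64, 64)` with the defaults
#'   yields 4096 features.
#' @param headHiddenWidth hidden width of the two-layer heads.
#' @param kOutputs number of confounders predicted by the adversarial head.
#' @return an [ArchitectureSpec].
#' @export
cfnetArchitecture <- function(inputShape, nStacks = 4L, kernelSize = 2L,
                              poolSize = 2L, nFiltersStart = 16L,
                              headHiddenWidth = 32L, kOutputs = 1L) {
  new("ArchitectureSpec", inputShape = as.integer(inputShape),
      nStacks = as.integer(nStacks), kernelSize = as.integer(kernelSize),
      poolSize = as.integer(poolSize),
      nFiltersStart = as.integer(nFiltersStart),
      headHiddenWidth = as.integer(headHiddenWidth),
      kOutputs = as.integer(kOutputs))
}

#' Build a confounder-free network model
#'
#' Initialises the three parameter groups (feature extractor, outcome
#' predictor head, confounder-prediction head) deterministically from the
#' seed. The feature extractor and predictor draws are independent of
#' whether the confounder head is included, so a baseline network
#' (`includeCP = FALSE`) starts bit-identically to the full model.
#'
#' @param arch an [ArchitectureSpec].
#' @param task `"classification"` (sigmoid-squashed scalar output) or
#'   `"regression"` (linear scalar output).
#' @param seed integer seed for the weight initialisation.
#' @param includeCP include the adversarial confounder head.
#' @return a [CFNetModel].
#' @export
buildModel <- function(arch, task = c("classification", "regression"),
                       seed = 1L, includeCP = TRUE) {
  task <- match.arg(task)
  validObject(arch)
  d <- archDims(arch)
  plan <- channelPlan(arch)
  koff <- prod(d$kdim)
  fw <- featureWidth(arch)
  withRNG(seed, {
    fe <- list()
    buffers <- list()
    cin <- 1L
    for (s in seq_len(arch@nStacks)) {
      cout <- plan[s]
      fanIn <- koff * cin
      fe[[nm("conv", s, "W")]] <-
        matrix(stats::rnorm(fanIn * cout, sd = sqrt(2 / fanIn)), fanIn, cout)
      fe[[nm("conv", s, "b")]] <- numeric(cout)
      fe[[nm("bn", s, "gamma")]] <- rep(1, cout)
      fe[[nm("bn", s, "beta")]] <- numeric(cout)
      buffers[[nm("bn", s, "mean")]] <- numeric(cout)
      buffers[[nm("bn", s, "var")]] <- rep(1, cout)
      cin <- cout
    }
    thetaP <- initHead(fw, arch@headHiddenWidth, 1L)
    thetaCP <- if (includeCP)
      initHead(fw, arch@headHiddenWidth, arch@kOutputs) else list()
    new("CFNetModel", arch = arch, task = task, thetaFE = fe,
        thetaP = thetaP, thetaCP = thetaCP, buffers = buffers)
  })
}

setMethod("show", "CFNetModel", function(object) {
  arch <- object@arch
  cat("CFNetModel (", object@task, ")\n", sep = "")
  cat("  input:", paste(arch@inputShape, collapse = "x"),
      "| stacks:", arch@nStacks,
      "| channels:", paste(channelPlan(arch), collapse = "/"),
      "| features:", featureWidth(arch), "\n")
  cat("  confounder head:",
      if (length(object@thetaCP)) sprintf("%d output(s)", arch@kOutputs)
      else "detached", "\n")
})

#' Prediction loss
#'
#' Mean binary cross-entropy for classification (predictions are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithm) or mean squared error for
#' regression, averaged over the batch.
#'
#' @param y observed outcomes.
#' @param yHat predictions; probabilities in `[0, 1]` for classification.
#' @param task `"classification"` or `"regression"`.
#' @return a single nonnegative number.
#' @examples
#' predictionLoss(c(1, 0), c(0.5, 0.5), "classification")  # log(2)
#' @export
predictionLoss <- function(y, yHat, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (length(y) != length(yHat)) stop("y and yHat must have equal length")
  if (task == "classification") {
    if (any(yHat < 0 | yHat > 1))
      stop("classification predictions must lie in [0, 1]")
    p <- pmin(pmax(yHat, 1e-7), 1 - 1e-7)
    mean(-y * log(p) - (1 - y) * log(1 - p))
  } else {
    mean((y - yHat)^2)
  }
}

# Squared Pearson correlation with analytic gradient with respect to the
# second argument. Variances below `eps` define the value (and gradient)
# as 0, so a collapsed prediction column exerts no adversarial gradient.
corr2WithGrad <- function(u, v, eps = 1e-8) {
  n <- length(u)
  u0 <- u - mean(u)
  v0 <- v - mean(v)
  suu <- sum(u0^2)
  svv <- sum(v0^2)
  if (suu / n < eps || svv / n < eps)
    return(list(value = 0, grad = numeric(n)))
  r <- sum(u0 * v0) / sqrt(suu * svv)
  grad <- 2 * r * (u0 / sqrt(suu * svv) - r * v0 / svv)
  list(value = r^2, grad = grad)
}

#' Squared Pearson correlation
#'
#' The dependence measure driven to zero by the adversarial update. If
#' either input has variance below `1e-8` the value is defined as 0 (a
#' degenerate mini-batch thereby contributes no adversarial gradient).
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return a number in `[0, 1]`.
#' @examples
#' squaredCorrelation(c(1, 2, 3), c(3, 1, 2))  # 0.25
#' @export
squaredCorrelation <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2L)
    stop("u and v must have equal length >= 2")
  corr2WithGrad(u, v)$value
}

#' Adversarial surrogate loss of confounder prediction
#'
#' The negative sum over confounders of the squared correlation between the
#' observed and predicted confounder, evaluated on the outcome-conditioned
#' cohort. Bounded in `[-k, 0]`; its maximisation by the feature extractor
#' drives the features toward mean independence of each confounder.
#'
#' @param C observed confounders, n x k matrix (rows are conditioned
#'   samples).
#' @param CHat predicted confounders, n x k matrix.
#' @return list with `L_cp` (the loss) and `corr2` (per-confounder squared
#'   correlations).
#' @export
confounderAdversarialLoss <- function(C, CHat) {
  C <- as.matrix(C)
  CHat <- as.matrix(CHat)
  if (!identical(dim(C), dim(CHat)))
    stop("C and CHat must have identical dimensions")
  if (nrow(C) < 2L) stop("at least two conditioned samples are required")
  corr2 <- vapply(seq_len(ncol(C)),
                  function(k) corr2WithGrad(C[, k], CHat[, k])$value,
                  numeric(1))
  names(corr2) <- colnames(C)
  list(L_cp = -sum(corr2), corr2 = corr2)
}

#' Overall min-max objective value
#'
#' `L_p - lambda * L_cp`: minimised over the feature extractor and predictor
#' parameters, maximised over the confounder head parameters.
#'
#' @param L_p prediction loss.
#' @param L_cp adversarial surrogate loss (in `[-k, 0]`).
#' @param lambda nonnegative trade-off weight.
#' @return a single number.
#' @export
objectiveValue <- function(L_p, L_cp, lambda) L_p - lambda * L_cp

# Evaluation-mode forward pass returning features and raw head output.
modelForward <- function(model, images, train = FALSE) {
  x <- stackImages(images)
  fw <- feForward(model, x, train = train, updateBuffers = FALSE)
  ph <- headForward(model@thetaP, fw$F)
  list(F = fw$F, logits = ph$out[, 1L], fw = fw, phCache = ph$cache)
}

#' Predict outcomes for new images
#'
#' Deterministic evaluation-mode forward pass (batch normalisation uses its
#' running statistics).
#'
#' @param model a trained [CFNetModel].
#' @param images a list of image arrays, or a single array.
#' @return numeric vector of predictions: probabilities in (0, 1) for
#'   classification, linear outputs for regression.
#' @export
predictCFNet <- function(model, images) {
  checkImageShape(model, images)
  out <- modelForward(model, images)$logits
  if (model@task == "classification") sigmoid(out) else out
}

#' Extract the learned feature vectors
#'
#' @param model a [CFNetModel].
#' @param images list of image arrays (or a single array).
#' @return numeric matrix, one row of features per image.
#' @export
extractFeatures <- function(model, images) {
  checkImageShape(model, images)
  modelForward(model, images)$F
}

checkImageShape <- function(model, images) {
  img <- if (is.list(images)) images[[1L]] else images
  if (!identical(as.integer(dim(img)), model@arch@inputShape))
    stop(sprintf("image shape (%s) does not match the architecture (%s)",
                 paste(dim(img), collapse = "x"),
                 paste(model@arch@inputShape, collapse = "x")))
  invisible(TRUE)
}

#' Gradient saliency map
#'
#' Absolute value of the gradient of the predictor's pre-threshold score
#' (the logit for classification) with respect to the input intensities;
#' large values mark voxels the prediction relies on.
#'
#' @param model a trained [CFNetModel].
#' @param image a single image array matching the architecture input shape.
#' @return nonnegative numeric array of the same shape as `image`.
#' @export
saliencyMap <- function(model, image) {
  checkImageShape(model, image)
  mf <- modelForward(model, image)
  hb <- headBackward(model@thetaP, mf$phCache, matrix(1, 1L, 1L))
  dx <- feBackward(model, mf$fw, hb$dF, needDx = TRUE)$dx
  dim(dx) <- model@arch@inputShape
  abs(dx)
}
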