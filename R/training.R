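#' Create a training configuration
#'
#' Defaults follow the reference regime: `lambda = 1`, batch size 64, Adam
#' with learning rate 2e-4. Set `lambda = 0` for a run whose feature
#' extractor receives no adversarial gradient, or `detachCP = TRUE` to drop
#' the confounder head entirely (baseline network).
#'
#' @param lambda nonnegative adversarial trade-off weight.
#' @param batchSize mini-batch size.
#' @param learningRate Adam learning rate.
#' @param maxIterations number of alternating iterations.
#' @param task `"classification"` or `"regression"`.
#' @param seed integer seed driving all batch sampling and augmentation.
#' @param augment apply random shift/rotation augmentation to each batch.
#' @param maxShift,maxRotationDeg augmentation bounds (see
#'   [augmentImage()]).
#' @param balanceClasses oversample the minority class to parity
#'   (classification only).
#' @param detachCP drop the confounder head.
#' @param cpSteps optimisation steps of the confounder head per iteration
#'   (sub-update 2). The head re-uses the conditioned batch's features, so
#'   extra steps are cheap; they keep the adversary close to its best
#'   response against the current feature extractor.
#' @param weightDecay L2 penalty on the feature extractor and predictor
#'   parameters (the adversarial head is never decayed, so the adversary is
#'   not weakened).
#' @param cpExactOutput refit the confounder head's output layer in closed
#'   form (ridge least squares on the conditioned batch) at the end of
#'   sub-update (2). The inner maximisation over the output layer is then
#'   solved exactly, so the feature extractor cannot evade a lagging
#'   adversary; by the envelope theorem the sub-update (3) gradient through
#'   the refit head is the gradient of the best-response surrogate loss.
#' @param advSteps number of feature-extractor adversarial sub-updates per
#'   iteration (repeats of sub-update 3, each against the refreshed best
#'   response when `cpExactOutput`).
#' @param condBatchSize conditioned-cohort batch size; `NA` uses the whole
#'   conditioned cohort each iteration (deterministic; bootstrap weights
#'   ignored), which removes the sampling-noise floor of the batch
#'   correlation.
#' @param advEvalMode `"train"`, `"eval"` or `"both"`: which
#'   batch-normalisation regime the adversary sees on the conditioned
#'   cohort. `"eval"` aligns the cleaned representation with the one used
#'   at prediction time; `"both"` alternates the adversarial sub-updates
#'   between the two regimes (they differ nonlinearly because pooling
#'   follows normalisation, so cleaning one does not imply cleaning the
#'   other).
#' @param selectBest return the snapshot of the second-half iteration with
#'   the weakest recorded feature-confounder dependence (smallest
#'   best-response correlation) rather than the final iterate; the
#'   alternating search oscillates around the saddle point, and the final
#'   iterate is an arbitrary point of that oscillation.
#' @return a [TrainingConfig].
#' @export
trainingConfig <- function(lambda = 1, batchSize = 64L, learningRate = 2e-4,
                           maxIterations = 100L,
                           task = c("classification", "regression"),
                           seed = 1L, augment = FALSE, maxShift = 1,
                           maxRotationDeg = 1, balanceClasses = TRUE,
                           detachCP = FALSE, cpSteps = 1L,
                           weightDecay = 0, cpExactOutput = FALSE,
                           advSteps = 1L, condBatchSize = NULL,
                           advEvalMode = c("train", "eval", "both"),
                           selectBest = FALSE) {
  advEvalMode <- match.arg(advEvalMode)
  task <- match.arg(task)
  new("TrainingConfig", lambda = lambda, batchSize = as.integer(batchSize),
      learningRate = learningRate, maxIterations = as.integer(maxIterations),
      task = task, seed = as.integer(seed), augment = augment,
      maxShift = maxShift, maxRotationDeg = maxRotationDeg,
      balanceClasses = balanceClasses, detachCP = detachCP,
      cpSteps = as.integer(cpSteps), weightDecay = weightDecay,
      cpExactOutput = cpExactOutput, advSteps = as.integer(advSteps),
      condBatchSize = if (is.null(condBatchSize)) NA_integer_
                      else as.integer(condBatchSize),
      advEvalMode = advEvalMode, selectBest = selectBest)
}

# ---- RNG streams -----------------------------------------------------------
# Two independent streams keep the conditioned-cohort sampling from
# perturbing the main batch stream, so a run with the confounder head
# detached consumes exactly the same main-stream draws as a full run.

newRngStream <- function(seed) {
  withRNG(seed, get(".Random.seed", envir = globalenv()))
}

runWithStream <- function(stream, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream, envir = globalenv())
  value <- fn()
  out <- get(".Random.seed", envir = globalenv())
  if (has) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  list(value = value, stream = out)
}

# ---- one alternating iteration --------------------------------------------

#' One three-step alternating update
#'
#' Executes the three sub-updates of the min-max objective in order:
#' (1) backpropagate the prediction loss on a batch from all training data,
#' updating the feature extractor and predictor head; (2) with the feature
#' extractor frozen, minimise the adversarial surrogate loss on a batch from
#' the outcome-conditioned cohort, updating the confounder head; (3) with
#' the confounder head frozen, maximise the surrogate loss (i.e. drive the
#' feature-confounder correlations toward zero), updating the feature
#' extractor. Each update has its own Adam state. Batch-normalisation
#' running statistics advance only in sub-update (1).
#'
#' @param state a [TrainState] (see [initTrainState()]).
#' @param batchAll list with `x` (image list or 5-d batch array) and `y`
#'   (outcomes), sampled from all training data.
#' @param batchCond list with `x` and `C` (confounder matrix), sampled from
#'   the `rho = 1` cohort; may be `NULL` when the confounder head is
#'   detached.
#' @param config a [TrainingConfig].
#' @param steps which sub-updates to run (default all three; running a
#'   subset is useful for verifying the freeze contract).
#' @param batchCondAdv optional second conditioned batch for sub-update
#'   (3); by default the batch of sub-update (2) is re-used. A fresh batch
#'   evaluates the adversary away from the data it was just fitted on,
#'   which directs the feature-extractor update at reproducible
#'   feature-confounder dependence rather than batch noise.
#' @return the updated [TrainState] with one loss record appended.
#' @export
trainStep <- function(state, batchAll, batchCond, config,
                      steps = c(1L, 2L, 3L), batchCondAdv = NULL) {
  model <- state@model
  hasCP <- length(model@thetaCP) > 0L
  if (!hasCP && config@lambda > 0)
    stop("lambda > 0 requires the confounder head (got a detached model)")
  if (hasCP && any(c(2L, 3L) %in% steps)) {
    if (is.null(batchCond) || !length(batchCond))
      stop("batchCond is required when the confounder head is attached")
    if (nrow(as.matrix(batchCond$C)) < 2L)
      stop("batchCond must contain at least two samples")
  }
  Lp <- NA_real_
  Lcp <- NA_real_
  corr2 <- rep(NA_real_, max(1L, model@arch@kOutputs))

  if (1L %in% steps) {
    x <- if (is.list(batchAll$x)) stackImages(batchAll$x) else batchAll$x
    y <- batchAll$y
    n <- length(y)
    fw <- feForward(model, x, train = TRUE, updateBuffers = TRUE)
    model@buffers <- fw$buffers
    ph <- headForward(model@thetaP, fw$F)
    if (model@task == "classification") {
      p <- sigmoid(ph$out[, 1L])
      Lp <- predictionLoss(y, p, "classification")
      dOut <- matrix((p - y) / n, ncol = 1L)
    } else {
      Lp <- predictionLoss(y, ph$out[, 1L], "regression")
      dOut <- matrix(2 * (ph$out[, 1L] - y) / n, ncol = 1L)
    }
    hb <- headBackward(model@thetaP, ph$cache, dOut)
    fe <- feBackward(model, fw, hb$dF)
    params <- c(prefixNames(model@thetaFE, "FE."),
                prefixNames(model@thetaP, "P."))
    grads <- c(prefixNames(fe$grads, "FE."), prefixNames(hb$grads, "P."))
    grads <- addDecay(grads, params, config@weightDecay)
    upd <- adamStep(params, grads, state@optState$g1, config@learningRate)
    state@optState$g1 <- upd$state
    model@thetaFE <- stripPrefix(upd$params, "FE.")
    model@thetaP <- stripPrefix(upd$params, "P.")
  }

  # Sub-updates (2) and (3) share the conditioned batch; since the feature
  # extractor is frozen in (2), its forward pass is computed once.
  fwCond <- NULL
  if (hasCP && any(c(2L, 3L) %in% steps)) {
    xc <- if (is.list(batchCond$x)) stackImages(batchCond$x) else batchCond$x
    C <- as.matrix(batchCond$C)
    fwCond <- feForward(model, xc, train = config@advEvalMode != "eval",
                        updateBuffers = FALSE)
  }

  if (hasCP && 2L %in% steps) {
    for (rep in seq_len(config@cpSteps)) {
      ch <- headForward(model@thetaCP, fwCond$F)
      dChat <- matrix(0, nrow(C), ncol(C))
      for (k in seq_len(ncol(C))) {
        g <- corr2WithGrad(C[, k], ch$out[, k])
        dChat[, k] <- -g$grad  # minimise L_cp = -sum corr^2
      }
      hb <- headBackward(model@thetaCP, ch$cache, dChat)
      upd <- adamStep(model@thetaCP, hb$grads, state@optState$g2,
                      config@learningRate)
      state@optState$g2 <- upd$state
      model@thetaCP <- upd$params
    }
    if (config@cpExactOutput)
      model@thetaCP <- refitCPOutput(model@thetaCP, fwCond$F, C)
  }

  if (hasCP && 3L %in% steps) {
    if (!is.null(batchCondAdv)) {
      xc3 <- if (is.list(batchCondAdv$x)) stackImages(batchCondAdv$x)
             else batchCondAdv$x
      C3 <- as.matrix(batchCondAdv$C)
      fw <- feForward(model, xc3, train = config@advEvalMode != "eval",
                      updateBuffers = FALSE)
    } else {
      xc3 <- xc
      C3 <- C
      fw <- fwCond
    }
    # The confounder head is frozen in this sub-update: repeated updates
    # evaluate the best response on a local copy without persisting it.
    cpLocal <- model@thetaCP
    for (rep in seq_len(config@advSteps)) {
      if (rep > 1L) {
        # the extractor moved: refresh the forward pass (and the best
        # response, when enabled) before the next adversarial update
        # In "both" mode the later updates attack the eval-mode
        # representation while the first attacked the train-mode one.
        trainMode <- switch(config@advEvalMode, train = TRUE, eval = FALSE,
                            both = FALSE)
        fw <- feForward(model, xc3, train = trainMode,
                        updateBuffers = FALSE)
        if (config@cpExactOutput)
          cpLocal <- refitCPOutput(cpLocal, fw$F, C3)
      }
      ch <- headForward(cpLocal, fw$F)
      dChat <- matrix(0, nrow(C3), ncol(C3))
      corr2 <- numeric(ncol(C3))
      for (k in seq_len(ncol(C3))) {
        g <- corr2WithGrad(C3[, k], ch$out[, k])
        corr2[k] <- g$value
        # maximise L_cp: minimise lambda * sum corr^2 w.r.t. theta_fe
        dChat[, k] <- config@lambda * g$grad
      }
      Lcp <- -sum(corr2)
      hb <- headBackward(cpLocal, ch$cache, dChat)
      fe <- feBackward(model, fw, hb$dF)
      g3 <- addDecay(fe$grads, model@thetaFE, config@weightDecay)
      upd <- adamStep(model@thetaFE, g3, state@optState$g3,
                      config@learningRate)
      state@optState$g3 <- upd$state
      model@thetaFE <- upd$params
    }
  }

  state@model <- model
  state@iteration <- state@iteration + 1L
  rec <- data.frame(iteration = state@iteration, L_p = Lp, L_cp = Lcp)
  for (k in seq_along(corr2))
    rec[[paste0("corr2_", k)]] <- corr2[k]
  state@lossHistory <- rbind(state@lossHistory, rec)
  state
}

# Snapshot-selection metric: summed ridge R^2 of each confounder on the
# evaluation-mode features of the conditioned cohort — the dependence a
# linear readout of the deployed representation can recover.
linearDependence <- function(model, x, C, ridge = 1e-3) {
  fw <- feForward(model, x, train = FALSE, updateBuffers = FALSE)
  F <- fw$F
  n <- nrow(F)
  s <- apply(F, 2L, stats::sd)
  keep <- s > 1e-10
  if (!any(keep)) return(0)
  Z <- scale(F[, keep, drop = FALSE])
  A <- crossprod(Z) + ridge * n * diag(ncol(Z))
  total <- 0
  for (k in seq_len(ncol(C))) {
    cc <- C[, k] - mean(C[, k])
    beta <- solve(A, crossprod(Z, cc))
    pred <- Z %*% beta
    denom <- sum(cc^2)
    if (denom > 0) total <- total + 1 - sum((cc - pred)^2) / denom
  }
  total
}

# Closed-form ridge refit of the confounder head's output layer: given the
# hidden activations H of the conditioned batch, (W2, b2) minimising the
# penalised squared error against each confounder column. Maximising
# correlation is invariant to the scale of the prediction, so the LS
# solution is the best-response direction.
refitCPOutput <- function(cpPar, F, C, ridge = 1e-3) {
  n <- nrow(F)
  H <- F %*% cpPar$W1 + rep(cpPar$b1, each = n)
  H <- H * (H > 0)
  hMean <- colMeans(H)
  Hc <- H - rep(hMean, each = n)
  cMean <- colMeans(C)
  Cc <- C - rep(cMean, each = n)
  A <- crossprod(Hc) + ridge * n * diag(ncol(H))
  beta <- solve(A, crossprod(Hc, Cc))
  cpPar$W2 <- beta
  cpPar$b2 <- as.numeric(cMean - crossprod(beta, hMean))
  cpPar
}

addDecay <- function(grads, params, wd) {
  if (wd > 0)
    for (name in names(grads))
      grads[[name]] <- grads[[name]] + wd * params[[name]]
  grads
}

prefixNames <- function(x, prefix) {
  names(x) <- paste0(prefix, names(x))
  x
}

stripPrefix <- function(x, prefix) {
  sel <- startsWith(names(x), prefix)
  out <- x[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

#' Initialise a training state
#'
#' @param model a [CFNetModel].
#' @param seed integer seed for the two batch-sampling streams.
#' @return a [TrainState] at iteration 0.
#' @export
initTrainState <- function(model, seed = 1L) {
  optState <- list(
    g1 = adamInit(c(prefixNames(model@thetaFE, "FE."),
                    prefixNames(model@thetaP, "P."))),
    g2 = if (length(model@thetaCP)) adamInit(model@thetaCP) else list(),
    g3 = adamInit(model@thetaFE))
  new("TrainState", model = model, iteration = 0L,
      lossHistory = data.frame(), optState = optState,
      rng = list(all = newRngStream(seed),
                 cond = newRngStream(seed + 1048576L)))
}

setMethod("show", "TrainState", function(object) {
  cat("TrainState: iteration", object@iteration, "\n")
  if (nrow(object@lossHistory)) {
    last <- object@lossHistory[nrow(object@lossHistory), ]
    cat(sprintf("  L_p = %.4f, L_cp = %.4f\n", last$L_p, last$L_cp))
  }
})

#' Train a confounder-free network
#'
#' Runs `maxIterations` alternating updates ([trainStep()]), sampling each
#' iteration one mini-batch from all training samples and (unless the head
#' is detached) one from the outcome-conditioned cohort (`rho = 1`,
#' respecting bootstrap weights). Fully deterministic for a fixed seed.
#'
#' @param dataset a [ConfoundedDataset]; a conditioning rule must already
#'   have been applied (some `rho = 1`) unless `detachCP`.
#' @param config a [TrainingConfig].
#' @param arch an [ArchitectureSpec]; by default derived from the dataset
#'   (image shape, one confounder-head output per confounder).
#' @param model optionally a pre-built [CFNetModel] to continue from.
#' @return a [TrainState] holding the trained model and the per-iteration
#'   loss history.
#' @export
fitCFNet <- function(dataset, config, arch = NULL, model = NULL) {
  stopifnot(is(dataset, "ConfoundedDataset"), is(config, "TrainingConfig"))
  if (is.null(arch))
    arch <- cfnetArchitecture(imageShape(dataset),
                              kOutputs = ncol(confounderValues(dataset)))
  if (is.null(model))
    model <- buildModel(arch, config@task, seed = config@seed,
                        includeCP = !config@detachCP)
  hasCP <- length(model@thetaCP) > 0L
  condIdx <- which(dataset@meta$rho == 1L)
  if (hasCP && !length(condIdx))
    stop("no rho = 1 samples: apply a conditioning rule before fitting")
  condW <- dataset@meta$weight[condIdx]

  pool <- seq_len(nSamples(dataset))
  if (config@task == "classification" && config@balanceClasses) {
    y <- dataset@meta$y
    n0 <- sum(y == 0)
    n1 <- sum(y == 1)
    if (n0 != n1 && n0 > 0L && n1 > 0L) {
      minority <- which(y == (if (n1 < n0) 1 else 0))
      pool <- c(pool, rep_len(minority, abs(n0 - n1)))
    }
  }

  state <- initTrainState(model, seed = config@seed)
  bs <- config@batchSize
  condFull <- NULL
  if (hasCP && is.na(config@condBatchSize)) {
    condFull <- list(x = stackImages(dataset@images[condIdx]),
                     C = dataset@confounders[condIdx, , drop = FALSE])
  }
  cbs <- if (is.na(config@condBatchSize)) bs else config@condBatchSize
  bestDep <- Inf
  bestModel <- NULL
  metricBatch <- NULL
  if (config@selectBest && hasCP)
    metricBatch <- list(x = stackImages(dataset@images[condIdx]),
                        C = dataset@confounders[condIdx, , drop = FALSE])
  for (it in seq_len(config@maxIterations)) {
    drawA <- runWithStream(state@rng$all, function() {
      idx <- if (length(pool) >= bs) pool[sample.int(length(pool), bs)]
             else pool[sample.int(length(pool), bs, replace = TRUE)]
      imgs <- dataset@images[idx]
      if (config@augment)
        imgs <- lapply(imgs, augmentImage, maxShift = config@maxShift,
                       maxRotationDeg = config@maxRotationDeg)
      list(x = imgs, y = dataset@meta$y[idx])
    })
    state@rng$all <- drawA$stream
    batchCond <- NULL
    batchCondAdv <- NULL
    if (hasCP && !is.null(condFull)) {
      batchCond <- condFull
    } else if (hasCP) {
      sampleCond <- function() {
        idx <- condIdx[sample.int(length(condIdx), cbs, replace = TRUE,
                                  prob = condW)]
        imgs <- dataset@images[idx]
        if (config@augment)
          imgs <- lapply(imgs, augmentImage, maxShift = config@maxShift,
                         maxRotationDeg = config@maxRotationDeg)
        list(x = imgs, C = dataset@confounders[idx, , drop = FALSE])
      }
      drawC <- runWithStream(state@rng$cond,
                             function() list(sampleCond(), sampleCond()))
      state@rng$cond <- drawC$stream
      batchCond <- drawC$value[[1L]]
      batchCondAdv <- drawC$value[[2L]]
    }
    state <- trainStep(state, drawA$value, batchCond, config,
                       batchCondAdv = batchCondAdv)
    if (config@selectBest && hasCP && it > config@maxIterations %/% 2L) {
      dep <- linearDependence(state@model, metricBatch$x, metricBatch$C)
      if (is.finite(dep) && dep < bestDep) {
        bestDep <- dep
        bestModel <- state@model
        state@selectedIteration <- it
      }
    }
  }
  if (config@selectBest && hasCP && !is.null(bestModel))
    state@model <- bestModel
  else
    state@selectedIteration <- state@iteration
  state
}

# ---- augmentation ----------------------------------------------------------

#' Randomly shift and rotate an image
#'
#' Draws integer translations within `±maxShift` per axis and rotations
#' within `±maxRotationDeg` per rotation axis (one for 2-d, three for 3-d)
#' from the current RNG, then applies the rotation (linear interpolation,
#' zero fill) followed by the shift (zero fill). The defaults mirror the
#' within-one-voxel / within-one-degree augmentation used for registered
#' MRI.
#'
#' @param image numeric 2-d or 3-d array.
#' @param maxShift maximum absolute translation per axis (pixels/voxels).
#' @param maxRotationDeg maximum absolute rotation per axis (degrees).
#' @return an array of the same shape.
#' @export
augmentImage <- function(image, maxShift = 1, maxRotationDeg = 1) {
  d <- dim(image)
  nd <- length(d)
  shift <- if (maxShift > 0)
    sample(seq(-floor(maxShift), floor(maxShift)), nd, replace = TRUE)
  else rep(0L, nd)
  nAng <- if (nd == 2L) 1L else 3L
  angles <- if (maxRotationDeg > 0)
    stats::runif(nAng, -maxRotationDeg, maxRotationDeg) else numeric(nAng)
  if (any(angles != 0)) image <- rotateImage(image, angles)
  if (any(shift != 0)) image <- shiftImage(image, shift)
  image
}

#' @rdname augmentImage
#' @param sample a [Sample]; its outcome, confounders and conditioning flag
#'   are returned unchanged.
#' @export
augmentSample <- function(sample, maxShift = 1, maxRotationDeg = 1) {
  stopifnot(is(sample, "Sample"))
  sample@image <- augmentImage(sample@image, maxShift, maxRotationDeg)
  sample
}

# Integer translation with zero fill; shift[i] moves content toward larger
# indices along axis i.
shiftImage <- function(image, shift) {
  d <- dim(image)
  out <- array(0, d)
  srcIdx <- dstIdx <- vector("list", length(d))
  for (a in seq_along(d)) {
    s <- shift[a]
    src <- seq_len(d[a]) - s
    keep <- src >= 1L & src <= d[a]
    srcIdx[[a]] <- src[keep]
    dstIdx[[a]] <- seq_len(d[a])[keep]
    if (!any(keep)) return(out)
  }
  if (length(d) == 2L)
    out[dstIdx[[1L]], dstIdx[[2L]]] <- image[srcIdx[[1L]], srcIdx[[2L]]]
  else
    out[dstIdx[[1L]], dstIdx[[2L]], dstIdx[[3L]]] <-
      image[srcIdx[[1L]], srcIdx[[2L]], srcIdx[[3L]]]
  out
}

# Rotation about the array centre with bi/tri-linear interpolation and zero
# fill. For 3-d the rotations about the three axes are composed in x-y-z
# order.
rotateImage <- function(image, anglesDeg) {
  d <- dim(image)
  nd <- length(d)
  th <- anglesDeg * pi / 180
  if (nd == 2L) {
    R <- matrix(c(cos(th[1L]), sin(th[1L]), -sin(th[1L]), cos(th[1L])), 2L)
  } else {
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
                c(-sin(th[2]), 0, cos(th[2])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rz %*% Ry %*% Rx
  }
  center <- (d + 1) / 2
  grid <- arrayInd(seq_len(prod(d)), d)
  src <- sweep(grid, 2L, center) %*% R
  src <- sweep(src, 2L, center, "+")
  f <- floor(src)
  w <- src - f
  out <- numeric(prod(d))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (ci in seq_len(nrow(corners))) {
    off <- corners[ci, ]
    pos <- sweep(f, 2L, off, "+")
    wt <- rep(1, nrow(pos))
    for (a in seq_len(nd))
      wt <- wt * (if (off[a] == 1L) w[, a] else 1 - w[, a])
    ok <- rep(TRUE, nrow(pos))
    for (a in seq_len(nd)) ok <- ok & pos[, a] >= 1 & pos[, a] <= d[a]
    if (!any(ok)) next
    lin <- pos[ok, 1L]
    mult <- 1
    for (a in seq_len(nd - 1L)) {
      mult <- mult * d[a]
      lin <- lin + (pos[ok, a + 1L] - 1) * mult
    }
    out[ok] <- out[ok] + wt[ok] * image[lin]
  }
  dim(out) <- d
  out
}
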