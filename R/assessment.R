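#' Classification metrics at a fixed operating point
#'
#' Positives are predictions at or above `threshold` (default the
#' uninformative operating point 0.5). Balanced accuracy is the mean of
#' sensitivity and specificity; precision is defined as 0 when nothing is
#' predicted positive; F1 is the harmonic mean of precision and recall (0
#' when both vanish).
#'
#' @param yTrue 0/1 labels (both classes must be present).
#' @param yProb predicted probabilities in `[0, 1]`.
#' @param threshold decision threshold.
#' @return named numeric vector: `bacc`, `precision`, `recall`, `f1`.
#' @examples
#' classificationMetrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'                       c(.9, .8, .7, .2, .6, .7, .1, .2, .3, .4))
#' @export
classificationMetrics <- function(yTrue, yProb, threshold = 0.5) {
  if (length(yTrue) != length(yProb))
    stop("yTrue and yProb must have equal length")
  if (any(yProb < 0 | yProb > 1)) stop("yProb must lie in [0, 1]")
  if (length(unique(yTrue)) < 2L)
    stop("both classes must be present (balanced accuracy is undefined)")
  pred <- as.integer(yProb >= threshold)
  tp <- sum(pred == 1L & yTrue == 1)
  fp <- sum(pred == 1L & yTrue == 0)
  fn <- sum(pred == 0L & yTrue == 1)
  tn <- sum(pred == 0L & yTrue == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- sens
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  c(bacc = (sens + spec) / 2, precision = precision, recall = recall,
    f1 = f1)
}

#' Per-stratum classification metrics
#'
#' Computes [classificationMetrics()] within each stratum (e.g. a median or
#' mean split of a confounder) and the largest pairwise balanced-accuracy
#' gap across strata — the fairness gap of the model with respect to the
#' stratifying variable. A single-class stratum is reported with `bacc = NA`
#' (precision and recall are still defined).
#'
#' @param yTrue,yProb as in [classificationMetrics()].
#' @param strata stratum label per sample (each stratum nonempty).
#' @param threshold decision threshold.
#' @return list with `perStratum` (data.frame: stratum, n, bacc, precision,
#'   recall, f1) and `baccGap`.
#' @export
stratifiedEval <- function(yTrue, yProb, strata, threshold = 0.5) {
  if (length(strata) != length(yTrue))
    stop("strata must label every sample")
  labs <- unique(strata)
  rows <- lapply(labs, function(s) {
    sel <- strata == s
    m <- tryCatch(classificationMetrics(yTrue[sel], yProb[sel], threshold),
                  error = function(e) {
                    pred <- as.integer(yProb[sel] >= threshold)
                    tp <- sum(pred == 1L & yTrue[sel] == 1)
                    fp <- sum(pred == 1L & yTrue[sel] == 0)
                    fn <- sum(pred == 0L & yTrue[sel] == 1)
                    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
                    rec <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
                    c(bacc = NA_real_, precision = prec, recall = rec,
                      f1 = NA_real_)
                  })
    data.frame(stratum = as.character(s), n = sum(sel), bacc = m[["bacc"]],
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], stringsAsFactors = FALSE)
  })
  perStratum <- do.call(rbind, rows)
  bacc <- perStratum$bacc[!is.na(perStratum$bacc)]
  gap <- if (length(bacc) >= 2L) max(bacc) - min(bacc) else NA_real_
  list(perStratum = perStratum, baccGap = gap)
}

#' Post-hoc confounder probe on frozen features
#'
#' Retrains a fresh two-layer confounder-prediction head (same architecture
#' as the adversarial head, new initialisation, fixed step budget) on the
#' frozen features of the training samples, then reports the Pearson
#' correlation between predicted and observed confounder values on the test
#' samples. A large correlation reveals residual confounder information in
#' the features.
#'
#' @param features n x d feature matrix (frozen; no gradient flows back).
#' @param c length-n confounder values.
#' @param trainIds,testIds disjoint integer row indices.
#' @param seed integer seed (initialisation and batch order).
#' @param hiddenWidth hidden width of the probe head.
#' @param steps Adam step budget.
#' @param batchSize probe mini-batch size.
#' @param learningRate probe Adam learning rate.
#' @return list with `r` (Pearson correlation on the test rows) and `p`
#'   (two-tailed p-value); a degenerate (constant) prediction yields a
#'   correlation of 0 with p-value 1.
#' @export
posthocProbe <- function(features, c, trainIds, testIds, seed = 1L,
                         hiddenWidth = 32L, steps = 2000L, batchSize = 64L,
                         learningRate = 1e-3) {
  features <- as.matrix(features)
  if (length(intersect(trainIds, testIds)))
    stop("trainIds and testIds must be disjoint")
  cTrain <- c[trainIds]
  if (stats::sd(cTrain) == 0)
    stop("confounder is constant on the training rows")
  mu <- colMeans(features[trainIds, , drop = FALSE])
  sdv <- apply(features[trainIds, , drop = FALSE], 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(features, 2L, mu), 2L, sdv, "/")
  cMu <- mean(cTrain)
  cSd <- stats::sd(cTrain)
  ct <- (c - cMu) / cSd
  nTrain <- length(trainIds)
  withRNG(seed, {
    par <- initHead(ncol(Z), hiddenWidth, 1L)
    st <- adamInit(par)
    for (i in seq_len(steps)) {
      idx <- trainIds[sample.int(nTrain, min(batchSize, nTrain))]
      hf <- headForward(par, Z[idx, , drop = FALSE])
      res <- hf$out[, 1L] - ct[idx]
      dOut <- matrix(2 * res / length(idx), ncol = 1L)
      hb <- headBackward(par, hf$cache, dOut)
      upd <- adamStep(par, hb$grads, st, learningRate)
      par <- upd$params
      st <- upd$state
    }
    pred <- headForward(par, Z[testIds, , drop = FALSE])$out[, 1L]
    if (stats::sd(pred) == 0 || stats::sd(ct[testIds]) == 0)
      return(list(r = 0, p = 1))
    ct0 <- stats::cor.test(pred, ct[testIds])
    list(r = unname(ct0$estimate), p = ct0$p.value)
  })
}

#' Distance correlation between features and a confounder
#'
#' Sample distance correlation computed from doubly centred pairwise
#' Euclidean distance matrices (the biased V-statistic estimator, bounded in
#' `[0, 1]`). Zero in population if and only if the two arguments are
#' independent.
#'
#' @param features n x d matrix (or length-n vector).
#' @param c length-n numeric vector.
#' @return a number in `[0, 1]`; 0 if either argument is constant.
#' @export
distanceCorrelation <- function(features, c) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 4L) stop("at least 4 samples are required")
  if (length(c) != n) stop("length(c) must equal nrow(features)")
  A <- dcenter(as.matrix(stats::dist(features)))
  B <- dcenter(as.matrix(stats::dist(c)))
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  min(1, max(0, sqrt(dcov2 / sqrt(dvarx * dvary))))
}

dcenter <- function(D) {
  rm <- rowMeans(D)
  sweep(sweep(D, 1L, rm), 2L, rm) + mean(D)
}

#' k-nearest-neighbour mutual information estimate
#'
#' Kraskov-type estimator (variant 1) of the mutual information between a
#' feature vector and a scalar, in nats: max-norm joint neighbourhoods with
#' Euclidean distances within the feature block. Marginals are standardised
#' and an imperceptible (1e-10 relative) deterministic jitter breaks exact
#' ties, so the estimator is well defined on bootstrap resamples. Estimates
#' are clipped at 0.
#'
#' @param features n x d matrix (or length-n vector).
#' @param c length-n numeric vector.
#' @param kNeighbors neighbourhood size (default 3).
#' @return nonnegative scalar (nats).
#' @export
mutualInformation <- function(features, c, kNeighbors = 3L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 20L) stop("at least 20 samples are required for a stable estimate")
  if (length(c) != n) stop("length(c) must equal nrow(features)")
  k <- as.integer(kNeighbors)
  std <- function(m) {
    s <- apply(m, 2L, stats::sd)
    s[s < 1e-12] <- 1
    sweep(m, 2L, s, "/")
  }
  X <- std(features)
  Y <- std(matrix(c, ncol = 1L))
  withRNG(760613L, {
    X <- X + matrix(stats::rnorm(length(X)), nrow(X)) * 1e-10
    Y <- Y + matrix(stats::rnorm(length(Y)), nrow(Y)) * 1e-10
  })
  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(Y))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  epsv <- apply(dz, 1L, function(row) sort.int(row, partial = k)[k])
  nx <- rowSums(dx < epsv) - 1L
  ny <- rowSums(dy < epsv) - 1L
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1L) + digamma(ny + 1L))
  max(0, mi)
}

#' Bootstrap distributions of the dependence measures
#'
#' Resamples the rows with replacement `nBoot` times and records the
#' distance correlation and mutual information of each replicate; two
#' models' replicate distributions can then be compared with
#' [compareDependence()].
#'
#' @param features n x d matrix.
#' @param c length-n confounder vector.
#' @param nBoot number of bootstrap replicates (>= 20).
#' @param seed integer seed.
#' @param kNeighbors passed to [mutualInformation()].
#' @return list with `dcor` and `mi` (replicate vectors) and `summary`
#'   (per-metric mean, sd, n).
#' @export
bootstrapDependence <- function(features, c, nBoot = 20L, seed = 1L,
                                kNeighbors = 3L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (nBoot < 20L) stop("nBoot must be >= 20")
  withRNG(seed, {
    dcorRep <- numeric(nBoot)
    miRep <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, replace = TRUE)
      dcorRep[b] <- distanceCorrelation(features[idx, , drop = FALSE],
                                        c[idx])
      miRep[b] <- mutualInformation(features[idx, , drop = FALSE], c[idx],
                                    kNeighbors)
    }
    list(dcor = dcorRep, mi = miRep,
         summary = data.frame(
           metric = c("dcor", "mi"),
           mean = c(mean(dcorRep), mean(miRep)),
           sd = c(stats::sd(dcorRep), stats::sd(miRep)),
           n = nBoot))
  })
}

#' Compare two models' bootstrap dependence distributions
#'
#' Two-sample t-tests on the replicate distributions produced by
#' [bootstrapDependence()].
#'
#' @param a,b lists returned by [bootstrapDependence()].
#' @return data.frame with one row per metric: mean difference (a - b),
#'   t statistic and two-tailed p-value.
#' @export
compareDependence <- function(a, b) {
  one <- function(x, y, metric) {
    tt <- stats::t.test(x, y)
    data.frame(metric = metric, meanDiff = mean(x) - mean(y),
               t = unname(tt$statistic), p = tt$p.value)
  }
  rbind(one(a$dcor, b$dcor, "dcor"), one(a$mi, b$mi, "mi"))
}

#' Assess a trained model on a test dataset
#'
#' Computes the full report: overall classification metrics, metrics per
#' stratum (mean split of the chosen confounder), metrics on a
#' confounder-matched subset built by [greedyMatch()], a post-hoc confounder
#' probe (trained on the conditioned group of `trainDataset`, evaluated on
#' the conditioned group of `dataset`), and the feature-confounder
#' dependence measures on the conditioned test group.
#'
#' @param model a trained [CFNetModel].
#' @param dataset the test [ConfoundedDataset].
#' @param trainDataset the training dataset (for the probe); `NULL` skips
#'   the probe.
#' @param confounderIndex confounder used for stratification, matching, the
#'   probe and the dependence measures.
#' @param conditionOn outcome group on which dependence is measured
#'   (default 0, i.e. controls).
#' @param nBoot bootstrap replicates for the dependence distributions (0
#'   skips the bootstrap).
#' @param probeSeed,probeSteps probe settings (see [posthocProbe()]).
#' @param matchPStop greedy-matching stopping threshold.
#' @return an [AssessmentReport].
#' @export
assessModel <- function(model, dataset, trainDataset = NULL,
                        confounderIndex = 1L, conditionOn = 0,
                        nBoot = 0L, probeSeed = 1L, probeSteps = 2000L,
                        matchPStop = 0.5) {
  stopifnot(is(model, "CFNetModel"), is(dataset, "ConfoundedDataset"))
  y <- outcomes(dataset)
  prob <- predictCFNet(model, dataset@images)
  cvals <- confounderValues(dataset)[, confounderIndex]

  if (model@task == "classification") {
    overall <- classificationMetrics(y, prob)
    strata <- ifelse(cvals <= mean(cvals), "low", "high")
    strat <- stratifiedEval(y, prob, strata)
    ms <- tryCatch(greedyMatch(dataset, confounderIndex, matchPStop),
                   error = function(e) NULL)
    matched <- if (!is.null(ms)) {
      idx <- match(c(ms@idsGroup0, ms@idsGroup1), sampleIds(dataset))
      m <- classificationMetrics(y[idx], prob[idx])
      data.frame(n = length(idx), bacc = m[["bacc"]],
                 precision = m[["precision"]], recall = m[["recall"]],
                 f1 = m[["f1"]], balanceP = ms@balancePValue)
    } else data.frame()
  } else {
    overall <- c(bacc = NA_real_, precision = NA_real_, recall = NA_real_,
                 f1 = NA_real_)
    strat <- list(perStratum = data.frame(), baccGap = NA_real_)
    matched <- data.frame()
  }

  condSel <- if (model@task == "classification") y == conditionOn
             else rep(TRUE, length(y))
  feats <- extractFeatures(model, dataset@images[condSel])
  cCond <- cvals[condSel]
  dcorV <- distanceCorrelation(feats, cCond)
  miV <- if (sum(condSel) >= 20L) mutualInformation(feats, cCond)
         else NA_real_
  boot <- list()
  if (nBoot >= 20L)
    boot <- bootstrapDependence(feats, cCond, nBoot, seed = probeSeed)

  posthocR <- NA_real_
  posthocP <- NA_real_
  if (!is.null(trainDataset)) {
    trSel <- if (model@task == "classification")
      outcomes(trainDataset) == conditionOn
      else rep(TRUE, nSamples(trainDataset))
    trFeats <- extractFeatures(model, trainDataset@images[trSel])
    allFeats <- rbind(trFeats, feats)
    allC <- c(confounderValues(trainDataset)[trSel, confounderIndex], cCond)
    pr <- posthocProbe(allFeats, allC, seq_len(nrow(trFeats)),
                       nrow(trFeats) + seq_len(nrow(feats)),
                       seed = probeSeed, steps = probeSteps,
                       hiddenWidth = model@arch@headHiddenWidth)
    posthocR <- pr$r
    posthocP <- pr$p
  }

  new("AssessmentReport", bacc = unname(overall[["bacc"]]),
      precision = unname(overall[["precision"]]),
      recall = unname(overall[["recall"]]), f1 = unname(overall[["f1"]]),
      perStratum = strat$perStratum, baccGap = strat$baccGap,
      matched = matched, posthocR = posthocR, posthocP = posthocP,
      dcor = dcorV, mi = miV, bootstrap = boot)
}

setMethod("show", "AssessmentReport", function(object) {
  cat("AssessmentReport\n")
  if (!is.na(object@bacc))
    cat(sprintf("  bacc %.3f | precision %.3f | recall %.3f | f1 %.3f\n",
                object@bacc, object@precision, object@recall, object@f1))
  if (!is.na(object@baccGap))
    cat(sprintf("  stratified bacc gap: %.3f\n", object@baccGap))
  if (nrow(object@matched))
    cat(sprintf("  matched subset (n = %d): bacc %.3f\n",
                object@matched$n, object@matched$bacc))
  cat(sprintf("  dependence: dcor %.3f | MI %.3f | probe r %.3f (p %.3g)\n",
              object@dcor, object@mi, object@posthocR, object@posthocP))
})

#' Convert an assessment report to a list (for JSON serialisation)
#'
#' @param report an [AssessmentReport].
#' @return a plain nested list.
#' @export
reportAsList <- function(report) {
  list(bacc = report@bacc, precision = report@precision,
       recall = report@recall, f1 = report@f1,
       bacc_gap = report@baccGap,
       per_stratum = report@perStratum,
       matched = report@matched,
       posthoc_r = report@posthocR, posthoc_p = report@posthocP,
       dcor = report@dcor, mi = report@mi,
       bootstrap = if (length(report@bootstrap))
         report@bootstrap$summary else NULL)
}
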