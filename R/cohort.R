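#' Create a conditioning rule
#'
#' Convenience constructors for [ConditioningRule-class] objects.
#'
#' @param groupValue outcome group (0 or 1) defining the conditioned cohort.
#' @param interval numeric `[low, high]` outcome interval, or `NULL` to
#'   compute the full width at half maximum of the outcome distribution from
#'   the training data.
#' @param perBinCount samples drawn per (bin x level) cell.
#' @param binWidth width of the contiguous outcome bins.
#' @param matchVariable name of the discrete variable balanced within bins
#'   (a confounder column or an extra covariate).
#' @return a [ConditioningRule-class].
#' @export
binaryConditioning <- function(groupValue = 0) {
  new("ConditioningRule", mode = "binary_group",
      groupValue = as.numeric(groupValue), interval = c(NA_real_, NA_real_),
      perBinCount = 1L, binWidth = 1, matchVariable = "")
}

#' @rdname binaryConditioning
#' @export
continuousConditioning <- function(interval = NULL, perBinCount = 1000L,
                                   binWidth = 10, matchVariable) {
  if (is.null(interval)) interval <- c(NA_real_, NA_real_)
  new("ConditioningRule", mode = "continuous_interval",
      groupValue = NA_real_, interval = as.numeric(interval),
      perBinCount = as.integer(perBinCount), binWidth = as.numeric(binWidth),
      matchVariable = matchVariable)
}

#' Condition the cohort on one outcome group
#'
#' Marks every sample of the chosen outcome group as a member of the
#' outcome-conditioned cohort (`rho = 1`) and clears the flag everywhere
#' else. Within a fixed outcome group the intrinsic outcome-confounder
#' correlation vanishes, so the adversarial head trained on this cohort
#' measures the direct feature-confounder association only. In a
#' case-control study one conditions on the group in which the
#' confounder-image relationship is physiologically meaningful (e.g. healthy
#' controls, `groupValue = 0`, for normal ageing).
#'
#' @param dataset a classification [ConfoundedDataset].
#' @param groupValue 0 or 1.
#' @return the dataset with updated `rho` flags.
#' @export
conditionBinary <- function(dataset, groupValue) {
  stopifnot(is(dataset, "ConfoundedDataset"))
  if (dataset@task != "classification")
    stop("conditionBinary() requires a classification task")
  if (!groupValue %in% c(0, 1)) stop("groupValue must be 0 or 1")
  sel <- dataset@meta$y == groupValue
  if (!any(sel))
    stop(sprintf("no samples with y = %g to condition on", groupValue))
  dataset@meta$rho <- as.integer(sel)
  dataset@meta$weight <- 1
  dataset
}

#' Full width at half maximum of an empirical distribution
#'
#' Builds a histogram at the given bin width, finds the maximum bin height h,
#' and returns the smallest and largest bin centres whose height is at least
#' h/2. Used to confine a continuous outcome to its well-populated range
#' before bootstrap matching.
#'
#' @param values numeric vector with at least two distinct values.
#' @param binWidth histogram bin width; default is the Freedman-Diaconis
#'   choice `2 IQR / n^(1/3)`.
#' @return numeric `[low, high]` with `low < high` (a single qualifying bin
#'   is widened to its edges).
#' @examples
#' fwhmInterval(rnorm(1e4, sd = 10))  # about 2.355 * 10 wide
#' @export
fwhmInterval <- function(values, binWidth = NULL) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("fwhmInterval() requires at least two distinct values")
  if (is.null(binWidth)) {
    binWidth <- 2 * stats::IQR(values) / length(values)^(1 / 3)
    if (binWidth <= 0) binWidth <- diff(range(values)) / 30
  }
  lo <- min(values)
  breaks <- seq(lo, max(values) + binWidth, by = binWidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE, right = FALSE)
  keep <- h$counts >= max(h$counts) / 2
  centers <- h$mids[keep]
  out <- c(min(centers), max(centers))
  if (out[1L] == out[2L]) out <- out + c(-0.5, 0.5) * binWidth
  out
}

#' Bootstrap a distribution-matched outcome-conditioned cohort
#'
#' For a continuous outcome, restricts to samples whose outcome lies in the
#' rule's interval, partitions that interval into contiguous bins of
#' `binWidth`, and within each bin draws `perBinCount` samples with
#' replacement from each level of the matching variable. The per-level
#' outcome distributions of the resampled cohort are matched by
#' construction. Samples drawn at least once get `rho = 1` and a sampling
#' weight equal to their draw count, so mini-batches from the conditioned
#' cohort respect the bootstrap multiset.
#'
#' @param dataset a regression [ConfoundedDataset].
#' @param rule a continuous-interval [ConditioningRule-class]; an `NA`
#'   interval is replaced by [fwhmInterval()] of the outcomes.
#' @param seed integer seed for the resampling.
#' @return list with `dataset` (rho flags and weights set), `ids` (the
#'   resampled id multiset, one element per draw), `interval` (the interval
#'   used) and `balanceP` (two-sample t-test p-value of the resampled
#'   outcome between the first two levels; near 1 by construction).
#' @export
bootstrapMatchedCohort <- function(dataset, rule, seed = 1L) {
  stopifnot(is(dataset, "ConfoundedDataset"), is(rule, "ConditioningRule"))
  if (dataset@task != "regression")
    stop("bootstrapMatchedCohort() requires a regression task")
  if (rule@mode != "continuous_interval")
    stop("rule must be in continuous_interval mode")
  y <- dataset@meta$y
  interval <- rule@interval
  if (anyNA(interval)) interval <- fwhmInterval(y, rule@binWidth)
  lev <- matchLevels(dataset, rule@matchVariable)
  breaks <- seq(interval[1L], interval[2L], by = rule@binWidth)
  if (breaks[length(breaks)] < interval[2L])
    breaks <- c(breaks, interval[2L])
  nBins <- length(breaks) - 1L
  if (nBins < 1L) stop("interval narrower than one bin")
  bin <- findInterval(y, breaks, rightmost.closed = TRUE)
  inRange <- bin >= 1L & bin <= nBins
  levels <- sort(unique(lev))
  draws <- withRNG(seed, {
    out <- integer(0)
    for (b in seq_len(nBins)) {
      for (l in levels) {
        cell <- which(inRange & bin == b & lev == l)
        if (!length(cell))
          stop(sprintf("empty cell: bin %d, level '%s'", b, l))
        out <- c(out, cell[sample.int(length(cell), rule@perBinCount,
                                      replace = TRUE)])
      }
    }
    out
  })
  counts <- tabulate(draws, nbins = nSamples(dataset))
  dataset@meta$rho <- as.integer(counts > 0L)
  dataset@meta$weight <- ifelse(counts > 0L, counts, 1)
  yDraw <- y[draws]
  lDraw <- lev[draws]
  balanceP <- tryCatch(
    stats::t.test(yDraw[lDraw == levels[1L]],
                  yDraw[lDraw == levels[2L]])$p.value,
    error = function(e) NA_real_)
  list(dataset = dataset, ids = dataset@meta$id[draws],
       interval = interval, balanceP = balanceP)
}

# Resolve the discrete matching variable: a confounder column or an extra
# covariate column.
matchLevels <- function(dataset, name) {
  if (name %in% colnames(dataset@confounders))
    return(dataset@confounders[, name])
  if (name %in% names(dataset@extra))
    return(dataset@extra[[name]])
  stop(sprintf("matching variable '%s' not found", name))
}

#' Greedy confounder matching of outcome groups
#'
#' Builds a confounder-matched evaluation subset: minority-group samples are
#' paired with unused majority-group samples in order of smallest absolute
#' confounder difference first (ties broken by smaller id, so the result is
#' invariant to input order). Pairs are accepted while the running
#' two-sample t-test p-value between the matched groups' confounder values
#' stays at or above `pStop`; matching also ends when every minority sample
#' is paired.
#'
#' @param dataset a classification [ConfoundedDataset] with both classes
#'   present.
#' @param confounderIndex column of the confounder matrix to match on.
#' @param pStop stopping threshold on the balance p-value, in (0, 1);
#'   default 0.5. Use a value close to 0 to force matching of the entire
#'   minority group.
#' @return a [MatchedSubset-class] with equal-sized groups.
#' @export
greedyMatch <- function(dataset, confounderIndex = 1L, pStop = 0.5) {
  stopifnot(is(dataset, "ConfoundedDataset"))
  if (dataset@task != "classification")
    stop("greedyMatch() requires a classification task")
  y <- dataset@meta$y
  ids <- dataset@meta$id
  cvals <- dataset@confounders[, confounderIndex]
  g0 <- which(y == 0)
  g1 <- which(y == 1)
  if (!length(g0) || !length(g1)) stop("both outcome groups must be nonempty")
  minority <- if (length(g1) <= length(g0)) g1 else g0
  majority <- if (length(g1) <= length(g0)) g0 else g1
  # order candidate pairs globally by |confounder difference|, then by ids
  dmat <- abs(outer(cvals[minority], cvals[majority], "-"))
  usedMin <- rep(FALSE, length(minority))
  usedMaj <- rep(FALSE, length(majority))
  pairs <- matrix(integer(0), ncol = 2L)
  cMin <- numeric(0)
  cMaj <- numeric(0)
  repeat {
    if (all(usedMin)) break
    sub <- dmat
    sub[usedMin, ] <- Inf
    sub[, usedMaj] <- Inf
    best <- min(sub)
    if (!is.finite(best)) break
    cand <- which(sub == best, arr.ind = TRUE)
    ord <- order(ids[minority][cand[, 1L]], ids[majority][cand[, 2L]])
    pick <- cand[ord[1L], ]
    newMin <- c(cMin, cvals[minority[pick[1L]]])
    newMaj <- c(cMaj, cvals[majority[pick[2L]]])
    p <- balancePValue(newMin, newMaj)
    if (nrow(pairs) >= 2L && !is.na(p) && p < pStop) break
    pairs <- rbind(pairs, c(minority[pick[1L]], majority[pick[2L]]))
    cMin <- newMin
    cMaj <- newMaj
    usedMin[pick[1L]] <- TRUE
    usedMaj[pick[2L]] <- TRUE
  }
  if (!nrow(pairs)) stop("no pairs could be matched")
  minIsG1 <- length(g1) <= length(g0)
  ids1 <- ids[pairs[, if (minIsG1) 1L else 2L]]
  ids0 <- ids[pairs[, if (minIsG1) 2L else 1L]]
  new("MatchedSubset", idsGroup0 = ids0, idsGroup1 = ids1,
      confounderName = colnames(dataset@confounders)[confounderIndex],
      balancePValue = balancePValue(cMin, cMaj))
}

# Two-sample t-test p-value with degenerate inputs mapped to 1 (fewer than
# two observations per group, or zero variance in both groups).
balancePValue <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' Normalise confounders to z-scores
#'
#' Transforms every confounder column to `(c - mean) / sd`, computing the
#' statistics over a reference subset only (typically the training split) so
#' held-out samples receive the identical transformation. The standard
#' deviation uses the population (n-denominator) convention.
#'
#' @param dataset a [ConfoundedDataset].
#' @param referenceIds ids whose samples define the statistics; default all.
#' @return list with `dataset` (confounders transformed), `center` and
#'   `scale` (named per-confounder statistics).
#' @export
zscoreConfounders <- function(dataset, referenceIds = sampleIds(dataset)) {
  stopifnot(is(dataset, "ConfoundedDataset"))
  idx <- match(referenceIds, dataset@meta$id)
  if (anyNA(idx)) stop("unknown reference id(s)")
  ref <- dataset@confounders[idx, , drop = FALSE]
  center <- colMeans(ref)
  scale <- sqrt(colMeans(sweep(ref, 2L, center)^2))
  if (any(scale < 1e-12))
    stop(sprintf("confounder '%s' is constant over the reference samples",
                 colnames(ref)[scale < 1e-12][1L]))
  dataset@confounders <- sweep(sweep(dataset@confounders, 2L, center), 2L,
                               scale, "/")
  list(dataset = dataset, center = center, scale = scale)
}
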