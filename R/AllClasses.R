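#' @import methods
NULL

#' A single imaging sample
#'
#' One image together with its outcome, confounder vector and conditioning
#' flag. Samples are normally handled collectively through a
#' [ConfoundedDataset]; this class exists mainly as the unit returned by
#' [getSample()] and consumed by [augmentSample()].
#'
#' @slot id character scalar, unique sample identifier.
#' @slot image numeric array, 2-d or 3-d, single channel.
#' @slot y numeric scalar outcome (0/1 for classification, real for
#'   regression).
#' @slot c numeric vector of k confounder values.
#' @slot rho integer conditioning flag in \{0, 1\}; 1 marks membership of the
#'   outcome-conditioned cohort used to train the adversarial head.
#' @export
setClass("Sample",
  representation(id = "character", image = "array", y = "numeric",
                 c = "numeric", rho = "integer"),
  prototype(rho = 0L))

setValidity("Sample", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  if (length(object@y) != 1L) msg <- c(msg, "'y' must be a single value")
  if (!object@rho %in% c(0L, 1L)) msg <- c(msg, "'rho' must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' A collection of confounded imaging samples
#'
#' Ordered collection of images with outcomes, a confounder matrix,
#' conditioning flags, resampling weights and (optionally) cross-validation
#' fold assignments. Structural consistency (matching lengths) is enforced on
#' construction; the scientific invariants (unique ids, uniform image shape,
#' binary labels for classification, ...) are checked by [validateDataset()],
#' which reports violations instead of raising so that defective datasets can
#' be diagnosed.
#'
#' @slot images list of numeric arrays, one per sample, all the same shape.
#' @slot meta data.frame with columns `id`, `y`, `rho`, `weight`.
#' @slot confounders numeric matrix, n x k, with column names.
#' @slot task `"classification"` or `"regression"`.
#' @slot splitAssignment named integer vector mapping sample id to fold
#'   index (length zero until [makeFolds()] is applied).
#' @slot extra data.frame of additional per-sample covariates (possibly
#'   zero columns), e.g. a discrete matching variable.
#' @export
setClass("ConfoundedDataset",
  representation(images = "list", meta = "data.frame",
                 confounders = "matrix", task = "character",
                 splitAssignment = "integer", extra = "data.frame"))

setValidity("ConfoundedDataset", function(object) {
  msg <- character()
  n <- length(object@images)
  if (nrow(object@meta) != n)
    msg <- c(msg, "meta must have one row per image")
  if (!all(c("id", "y", "rho", "weight") %in% names(object@meta)))
    msg <- c(msg, "meta must contain columns id, y, rho, weight")
  if (nrow(object@confounders) != n)
    msg <- c(msg, "confounder matrix must have one row per image")
  if (!object@task %in% c("classification", "regression"))
    msg <- c(msg, "task must be 'classification' or 'regression'")
  if (nrow(object@extra) && nrow(object@extra) != n)
    msg <- c(msg, "extra covariates must have one row per image")
  if (length(msg)) msg else TRUE
})

#' Rule defining the outcome-conditioned cohort
#'
#' For binary outcomes the cohort is one outcome group (e.g. the controls);
#' for continuous outcomes it is the set of samples whose outcome falls in an
#' interval (typically the FWHM of the outcome distribution), resampled so
#' that the outcome distribution is matched across the levels of a discrete
#' variable.
#'
#' @slot mode `"binary_group"`, `"continuous_interval"` or `"all"`.
#' @slot groupValue 0 or 1 (binary mode).
#' @slot interval numeric length-2 `[low, high]` (continuous mode); may be
#'   `NA` to request computation from the data via [fwhmInterval()].
#' @slot perBinCount samples drawn per (bin x level) cell (continuous mode).
#' @slot binWidth width of the contiguous outcome bins (continuous mode).
#' @slot matchVariable name of the discrete variable balanced within bins.
#' @export
setClass("ConditioningRule",
  representation(mode = "character", groupValue = "numeric",
                 interval = "numeric", perBinCount = "integer",
                 binWidth = "numeric", matchVariable = "character"))

setValidity("ConditioningRule", function(object) {
  msg <- character()
  if (!object@mode %in% c("binary_group", "continuous_interval", "all"))
    msg <- c(msg, "mode must be binary_group, continuous_interval or all")
  if (object@mode == "binary_group" && !object@groupValue %in% c(0, 1))
    msg <- c(msg, "groupValue must be 0 or 1")
  if (object@mode == "continuous_interval") {
    if (length(object@interval) != 2L)
      msg <- c(msg, "interval must have length 2")
    if (length(object@perBinCount) != 1L || is.na(object@perBinCount) ||
        object@perBinCount < 1L)
      msg <- c(msg, "perBinCount must be a positive integer")
    if (length(object@binWidth) != 1L || is.na(object@binWidth) ||
        object@binWidth <= 0)
      msg <- c(msg, "binWidth must be positive")
    if (!nzchar(object@matchVariable))
      msg <- c(msg, "matchVariable is required in continuous mode")
  }
  if (length(msg)) msg else TRUE
})

#' Architecture descriptor for the three subnetworks
#'
#' The feature extractor is a stack of convolution / ReLU / batch
#' normalisation / max-pooling blocks with 2x2 (2x2x2 in 3-d) kernels and
#' pooling; both heads are two-layer fully connected networks reading the
#' flattened feature vector. The channel plan doubles from `nFiltersStart`
#' for the first three stacks and then stays constant, so a 64^3 volume with
#' 4 stacks starting at 16 filters yields 4^3 x 64 = 4096 features.
#'
#' @slot inputShape integer vector, length 2 or 3.
#' @slot nStacks number of convolution stacks (default 4).
#' @slot kernelSize convolution kernel edge (default 2).
#' @slot poolSize pooling factor per axis (default 2).
#' @slot nFiltersStart channels of the first stack (default 16).
#' @slot headHiddenWidth hidden width of the two-layer heads (default 32).
#' @slot kOutputs outputs of the confounder head (= number of confounders).
#' @export
setClass("ArchitectureSpec",
  representation(inputShape = "integer", nStacks = "integer",
                 kernelSize = "integer", poolSize = "integer",
                 nFiltersStart = "integer", headHiddenWidth = "integer",
                 kOutputs = "integer"))

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  nd <- length(object@inputShape)
  if (!nd %in% c(2L, 3L))
    msg <- c(msg, "inputShape must have length 2 or 3")
  pf <- object@poolSize^object@nStacks
  if (any(object@inputShape %% pf != 0L))
    msg <- c(msg, sprintf(
      "each input dimension must be divisible by poolSize^nStacks (= %d)", pf))
  if (object@kOutputs < 1L) msg <- c(msg, "kOutputs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' Defaults mirror the reference training regime: trade-off weight
#' `lambda = 1`, batch size 64 and Adam with learning rate 2e-4. `lambda = 0`
#' reduces the objective to the plain prediction loss; combined with
#' `detachCP = TRUE` the adversarial head is removed entirely, giving the
#' baseline convolutional network.
#'
#' @slot lambda nonnegative trade-off weight of the adversarial term.
#' @slot batchSize mini-batch size.
#' @slot learningRate Adam learning rate (shared by all three updates).
#' @slot maxIterations number of alternating iterations.
#' @slot task `"classification"` or `"regression"`.
#' @slot seed integer seed driving all batch sampling and augmentation.
#' @slot augment logical; random shift/rotation augmentation of each batch.
#' @slot maxShift maximum augmentation translation (pixels/voxels per axis).
#' @slot maxRotationDeg maximum augmentation rotation (degrees per axis).
#' @slot balanceClasses logical; oversample the minority class to parity
#'   (classification only).
#' @slot detachCP logical; drop the confounder head (baseline network).
#' @slot cpSteps number of optimisation steps the confounder head takes
#'   within sub-update (2) of each iteration (default 1). Larger values
#'   keep the adversary near its best response, which matters on short
#'   iteration budgets.
#' @slot weightDecay L2 penalty applied to the feature extractor and
#'   predictor parameters (never to the adversarial head). Besides the
#'   usual regularisation, decay shrinks feature components that the
#'   predictor does not use, which helps the adversarial update eliminate
#'   residual confounder information.
#' @slot cpExactOutput refit the confounder head's output layer in closed
#'   form (ridge least squares) at the end of sub-update (2), so the
#'   adversary is at its best response given its hidden layer.
#' @slot advSteps number of executions of the feature-extractor adversarial
#'   sub-update (3) per iteration.
#' @slot condBatchSize size of the conditioned-cohort batch; `NA` evaluates
#'   the adversarial loss on the entire conditioned cohort (deterministic,
#'   resampling weights ignored).
#' @slot advEvalMode batch-normalisation mode of the conditioned-cohort
#'   passes: `"train"` (batch statistics), `"eval"` (running statistics, the
#'   representation deployed at test time) or `"both"` (alternating
#'   adversarial sub-updates attack each in turn).
#' @slot selectBest return the parameter snapshot from the iteration (in
#'   the second half of training) with the weakest recorded
#'   feature-confounder dependence, instead of the final iterate. The
#'   saddle-point search oscillates; the snapshot closest to the saddle is
#'   a better estimate than wherever the trajectory happens to stop.
#' @export
setClass("TrainingConfig",
  representation(lambda = "numeric", batchSize = "integer",
                 learningRate = "numeric", maxIterations = "integer",
                 task = "character", seed = "integer", augment = "logical",
                 maxShift = "numeric", maxRotationDeg = "numeric",
                 balanceClasses = "logical", detachCP = "logical",
                 cpSteps = "integer", weightDecay = "numeric",
                 cpExactOutput = "logical", advSteps = "integer",
                 condBatchSize = "integer", advEvalMode = "character",
                 selectBest = "logical"))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@batchSize < 2L) msg <- c(msg, "batchSize must be >= 2")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (object@cpSteps < 1L) msg <- c(msg, "cpSteps must be >= 1")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (object@advSteps < 1L) msg <- c(msg, "advSteps must be >= 1")
  if (!object@task %in% c("classification", "regression"))
    msg <- c(msg, "task must be 'classification' or 'regression'")
  if (length(msg)) msg else TRUE
})

#' The three-subnetwork confounder-free model
#'
#' Holds the three disjoint parameter groups: `thetaFE` (feature extractor),
#' `thetaP` (outcome predictor head) and `thetaCP` (confounder-prediction
#' head), plus batch-normalisation running statistics (`buffers`, which are
#' state, not trainable parameters).
#'
#' @slot arch an [ArchitectureSpec].
#' @slot task `"classification"` or `"regression"`.
#' @slot thetaFE named list of conv weight/bias and batch-norm gamma/beta.
#' @slot thetaP named list of the predictor head parameters.
#' @slot thetaCP named list of the confounder head parameters (empty when
#'   the head is detached).
#' @slot buffers named list of batch-norm running means/variances.
#' @export
setClass("CFNetModel",
  representation(arch = "ArchitectureSpec", task = "character",
                 thetaFE = "list", thetaP = "list", thetaCP = "list",
                 buffers = "list"))

#' Optimisation state of a model being trained
#'
#' @slot model the current [CFNetModel].
#' @slot iteration iterations completed.
#' @slot lossHistory data.frame with one row per iteration: `iteration`,
#'   `L_p`, `L_cp` and one `corr2_<name>` column per confounder.
#' @slot optState Adam moment estimates for the three update groups.
#' @slot rng list of two RNG stream states (`all`, `cond`) so that the
#'   conditioned-cohort sampling never perturbs the main batch stream.
#' @slot selectedIteration iteration whose parameter snapshot `model`
#'   holds (equals `iteration` unless snapshot selection was enabled).
#' @export
setClass("TrainState",
  representation(model = "CFNetModel", iteration = "integer",
                 lossHistory = "data.frame", optState = "list",
                 rng = "list", selectedIteration = "integer"),
  prototype(selectedIteration = NA_integer_))

#' A confounder-matched evaluation subset
#'
#' Equal-sized outcome groups matched on one confounder, as produced by
#' [greedyMatch()]. Accuracy measured on such a subset cannot be inflated by
#' confounder leakage.
#'
#' @slot idsGroup0,idsGroup1 matched sample ids (outcome 0 / outcome 1).
#' @slot confounderName name of the matched confounder.
#' @slot balancePValue two-sample t-test p-value between the matched groups'
#'   confounder values (1 when the test is degenerate, e.g. identical
#'   constants).
#' @export
setClass("MatchedSubset",
  representation(idsGroup0 = "character", idsGroup1 = "character",
                 confounderName = "character", balancePValue = "numeric"))

setValidity("MatchedSubset", function(object) {
  msg <- character()
  if (length(object@idsGroup0) != length(object@idsGroup1))
    msg <- c(msg, "matched groups must have equal size")
  ids <- c(object@idsGroup0, object@idsGroup1)
  if (anyDuplicated(ids)) msg <- c(msg, "no id may appear twice")
  if (length(msg)) msg else TRUE
})

#' Specification of the synthetic confounded-image generator
#'
#' Emulates a confounded imaging study with known ground truth: an outcome
#' signal of amplitude `yEffect` in region A, a confounder signal of
#' amplitude `cEffect` in a disjoint region B, and a tunable intrinsic
#' outcome-confounder association `ycAssociation` (the sample correlation
#' between y and c approaches this value). See the methods vignette for the
#' generative model.
#'
#' @slot n number of samples.
#' @slot imageShape integer vector, length 2 or 3.
#' @slot task `"classification"` or `"regression"`.
#' @slot yEffect outcome signal amplitude (mu_y).
#' @slot cEffect confounder signal amplitude (mu_c).
#' @slot ycAssociation intrinsic y-c association alpha in [-1, 1].
#' @slot noiseSd standard deviation of the additive Gaussian pixel noise.
#' @slot maskA,maskB disjoint logical arrays marking the outcome and
#'   confounder regions.
#' @slot yInterval outcome range for regression tasks.
#' @slot seed integer seed.
#' @export
setClass("GeneratorSpec",
  representation(n = "integer", imageShape = "integer", task = "character",
                 yEffect = "numeric", cEffect = "numeric",
                 ycAssociation = "numeric", noiseSd = "numeric",
                 maskA = "array", maskB = "array", yInterval = "numeric",
                 seed = "integer"))

setValidity("GeneratorSpec", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (!length(object@imageShape) %in% c(2L, 3L))
    msg <- c(msg, "imageShape must have length 2 or 3")
  if (abs(object@ycAssociation) > 1)
    msg <- c(msg, "ycAssociation must lie in [-1, 1]")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (!identical(dim(object@maskA), object@imageShape) ||
      !identical(dim(object@maskB), object@imageShape))
    msg <- c(msg, "masks must have the image shape")
  else {
    if (!any(object@maskA) || !any(object@maskB))
      msg <- c(msg, "masks must be nonempty")
    if (any(object@maskA & object@maskB))
      msg <- c(msg, "masks A and B must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Assessment report for a trained model
#'
#' Prediction metrics (overall, per stratum and on a confounder-matched
#' subset) together with feature-confounder dependence statistics.
#'
#' @slot bacc,precision,recall,f1 overall classification metrics in [0, 1].
#' @slot perStratum data.frame of per-stratum metrics.
#' @slot baccGap largest pairwise balanced-accuracy gap across strata.
#' @slot matched data.frame of metrics on the confounder-matched subset (zero
#'   rows when not computed).
#' @slot posthocR,posthocP Pearson correlation (and p-value) of a freshly
#'   trained confounder probe on frozen features.
#' @slot dcor distance correlation between features and confounder.
#' @slot mi k-nearest-neighbour mutual information estimate (nats).
#' @slot bootstrap list of bootstrap replicate summaries.
#' @export
setClass("AssessmentReport",
  representation(bacc = "numeric", precision = "numeric", recall = "numeric",
                 f1 = "numeric", perStratum = "data.frame",
                 baccGap = "numeric", matched = "data.frame",
                 posthocR = "numeric", posthocP = "numeric",
                 dcor = "numeric", mi = "numeric", bootstrap = "list"))
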