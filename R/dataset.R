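#' Construct a confounded imaging dataset
#'
#' @param images list of numeric arrays (2-d or 3-d, single channel), one per
#'   sample, all of identical shape.
#' @param y numeric outcome vector (0/1 for classification).
#' @param confounders numeric matrix (n x k) or vector (k = 1) of confounder
#'   values; column names are kept, defaulting to `c_1, ..., c_k`.
#' @param ids character sample identifiers; default `s1, ..., sn`.
#' @param task `"classification"` or `"regression"`.
#' @param extra optional data.frame of additional per-sample covariates.
#'
#' @return A [ConfoundedDataset] with all conditioning flags at 0 and unit
#'   sampling weights.
#' @examples
#' imgs <- replicate(4, array(rnorm(16 * 16), c(16, 16)), simplify = FALSE)
#' ds <- ConfoundedDataset(imgs, y = c(0, 1, 0, 1), confounders = rnorm(4))
#' nSamples(ds)
#' @export
ConfoundedDataset <- function(images, y,
                              confounders,
                              ids = paste0("s", seq_along(images)),
                              task = c("classification", "regression"),
                              extra = NULL) {
  task <- match.arg(task)
  n <- length(images)
  if (is.null(dim(confounders)))
    confounders <- matrix(as.numeric(confounders), ncol = 1L)
  confounders <- as.matrix(confounders)
  storage.mode(confounders) <- "double"
  if (is.null(colnames(confounders)))
    colnames(confounders) <- paste0("c_", seq_len(ncol(confounders)))
  meta <- data.frame(id = as.character(ids), y = as.numeric(y),
                     rho = 0L, weight = 1, stringsAsFactors = FALSE)
  if (is.null(extra)) extra <- data.frame(row.names = seq_len(n))
  new("ConfoundedDataset", images = images, meta = meta,
      confounders = confounders, task = task,
      splitAssignment = integer(0), extra = extra)
}

#' Accessors for ConfoundedDataset
#'
#' @param x a [ConfoundedDataset].
#' @param i sample index.
#' @return `nSamples` the number of samples; `sampleIds`, `outcomes`,
#'   `rhoFlags`, `sampleWeights` per-sample vectors; `confounderValues` the
#'   n x k confounder matrix; `confounderNames` its column names; `taskType`
#'   the task string; `imageShape` the common image dimensions;
#'   `foldAssignment` the named fold vector (empty before [makeFolds()]);
#'   `getSample` a [Sample].
#' @name ConfoundedDataset-accessors
#' @aliases nSamples sampleIds outcomes confounderValues confounderNames
#'   rhoFlags sampleWeights taskType imageShape foldAssignment getSample
NULL

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("nSamples", "ConfoundedDataset", function(x) length(x@images))

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("sampleIds", "ConfoundedDataset", function(x) x@meta$id)

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("outcomes", "ConfoundedDataset", function(x) x@meta$y)

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("confounderValues", "ConfoundedDataset", function(x) x@confounders)

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("confounderNames", "ConfoundedDataset",
          function(x) colnames(x@confounders))

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("rhoFlags", "ConfoundedDataset", function(x) x@meta$rho)

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("sampleWeights", "ConfoundedDataset", function(x) x@meta$weight)

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("taskType", "ConfoundedDataset", function(x) x@task)

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("imageShape", "ConfoundedDataset", function(x) {
  if (!length(x@images)) return(integer(0))
  dim(x@images[[1L]])
})

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("foldAssignment", "ConfoundedDataset",
          function(x) x@splitAssignment)

#' @rdname ConfoundedDataset-accessors
#' @export
setMethod("getSample", "ConfoundedDataset", function(x, i) {
  new("Sample", id = x@meta$id[i], image = x@images[[i]], y = x@meta$y[i],
      c = x@confounders[i, ], rho = as.integer(x@meta$rho[i]))
})

setMethod("show", "ConfoundedDataset", function(object) {
  cat("ConfoundedDataset:", nSamples(object), "samples,",
      ncol(object@confounders), "confounder(s),",
      paste(imageShape(object), collapse = "x"), "images,",
      object@task, "task\n")
  cat("  conditioned (rho = 1):", sum(object@meta$rho), "samples\n")
  if (length(object@splitAssignment))
    cat("  folds:", paste(table(object@splitAssignment), collapse = "/"), "\n")
})

#' Subset a dataset by sample index or id
#'
#' @param x a [ConfoundedDataset].
#' @param i integer, logical or character (id) index. Duplicated indices are
#'   allowed and yield resampled datasets (ids are made unique by suffixing).
#' @param j,...,drop ignored.
#' @return a [ConfoundedDataset].
#' @export
setMethod("[", "ConfoundedDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@meta$id)
  if (is.logical(i)) i <- which(i)
  ids <- make.unique(x@meta$id[i])
  out <- new("ConfoundedDataset",
             images = x@images[i],
             meta = transform(x@meta[i, , drop = FALSE], id = ids),
             confounders = x@confounders[i, , drop = FALSE],
             task = x@task,
             splitAssignment = integer(0),
             extra = x@extra[i, , drop = FALSE])
  rownames(out@meta) <- NULL
  rownames(out@extra) <- NULL
  out
})

#' Validate dataset invariants
#'
#' Checks the scientific invariants of a dataset and reports violations
#' without raising: unique ids, at least one confounder, finite values,
#' uniform single-channel image shape (2-d or 3-d), conditioning flags in
#' \{0, 1\}, and 0/1 outcomes covering both classes for classification.
#'
#' @param dataset a [ConfoundedDataset].
#' @return character vector of violation descriptions; empty if all
#'   invariants hold.
#' @examples
#' imgs <- replicate(4, array(0, c(8, 8)), simplify = FALSE)
#' ds <- ConfoundedDataset(imgs, c(0, 1, 0, 1), rnorm(4))
#' validateDataset(ds)  # character(0)
#' @export
validateDataset <- function(dataset) {
  stopifnot(is(dataset, "ConfoundedDataset"))
  v <- character()
  ids <- dataset@meta$id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    v <- c(v, sprintf("duplicate id '%s'", dup))
  if (ncol(dataset@confounders) < 1L)
    v <- c(v, "at least one confounder column is required (k >= 1)")
  if (length(dataset@images)) {
    ref <- dim(dataset@images[[1L]])
    for (i in seq_along(dataset@images)) {
      d <- dim(dataset@images[[i]])
      if (is.null(d) || !length(d) %in% c(2L, 3L))
        v <- c(v, sprintf(
          "sample '%s': image must be a single-channel 2-d or 3-d array",
          ids[i]))
      else if (!identical(d, ref))
        v <- c(v, sprintf("sample '%s': image shape differs from sample '%s'",
                          ids[i], ids[1L]))
      if (anyNA(dataset@images[[i]]) || any(!is.finite(dataset@images[[i]])))
        v <- c(v, sprintf("sample '%s': image contains non-finite values",
                          ids[i]))
    }
  }
  if (anyNA(dataset@confounders) || any(!is.finite(dataset@confounders)))
    v <- c(v, "confounder matrix contains non-finite values")
  bad <- !dataset@meta$rho %in% c(0L, 1L)
  if (any(bad))
    v <- c(v, sprintf("sample '%s': rho flag must be 0 or 1", ids[bad]))
  if (dataset@task == "classification") {
    y <- dataset@meta$y
    off <- !y %in% c(0, 1)
    if (any(off))
      v <- c(v, sprintf(
        "sample '%s': classification outcome must be 0 or 1 (got %g)",
        ids[off], y[off]))
    else if (length(unique(y)) < 2L)
      v <- c(v, "classification outcome must take both values 0 and 1")
  }
  v
}

#' Assign cross-validation folds
#'
#' Partitions the samples into `nFolds` folds. For classification the folds
#' are stratified by outcome, so each fold carries the per-class count up to
#' a difference of one. The same seed always yields the same assignment.
#'
#' @param dataset a [ConfoundedDataset].
#' @param nFolds number of folds (>= 2, <= number of samples).
#' @param seed integer seed.
#' @return the dataset with its `splitAssignment` slot filled (a named
#'   integer vector, id -> fold in `1:nFolds`).
#' @export
makeFolds <- function(dataset, nFolds, seed) {
  stopifnot(is(dataset, "ConfoundedDataset"))
  n <- nSamples(dataset)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  if (nFolds > n) stop("nFolds must not exceed the number of samples")
  fold <- integer(n)
  withRNG(seed, {
    if (dataset@task == "classification") {
      for (cls in unique(dataset@meta$y)) {
        idx <- which(dataset@meta$y == cls)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(nFolds), length(idx))
      }
    } else {
      idx <- sample.int(n)
      fold[idx] <- rep_len(seq_len(nFolds), n)
    }
  })
  names(fold) <- dataset@meta$id
  dataset@splitAssignment <- fold
  dataset
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
withRNG <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
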