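# Reading and writing datasets, checkpoints and run artefacts.
#
# On-disk layout: one metadata CSV with header id,y,c_1,...,c_k[,extra...]
# plus an image directory holding <id>.nii.gz (NIfTI-1) or <id>.png
# (8-bit grayscale with an affine intensity rescale recorded in the
# metadata columns img_offset/img_scale).

#' Write a dataset to disk
#'
#' @param dataset a [ConfoundedDataset].
#' @param dir output directory (created if missing); images go to
#'   `dir/images`, metadata to `dir/metadata.csv`.
#' @param format `"nifti"` (lossless, default, 2-d images are written as
#'   single-slice volumes) or `"png"` (2-d only; 8-bit quantisation with the
#'   rescale recorded in the metadata).
#' @return the directory, invisibly.
#' @export
writeConfoundedDataset <- function(dataset, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  stopifnot(is(dataset, "ConfoundedDataset"))
  imgDir <- file.path(dir, "images")
  dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(id = dataset@meta$id, y = dataset@meta$y)
  cf <- dataset@confounders
  for (j in seq_len(ncol(cf))) meta[[colnames(cf)[j]]] <- cf[, j]
  if (ncol(dataset@extra)) meta <- cbind(meta, dataset@extra)
  meta$rho <- dataset@meta$rho
  if (format == "png") {
    if (length(imageShape(dataset)) != 2L)
      stop("PNG output requires 2-d images")
    meta$img_offset <- NA_real_
    meta$img_scale <- NA_real_
    for (i in seq_len(nSamples(dataset))) {
      img <- dataset@images[[i]]
      lo <- min(img)
      hi <- max(img)
      scale <- if (hi > lo) hi - lo else 1
      png::writePNG((img - lo) / scale,
                    file.path(imgDir, paste0(meta$id[i], ".png")))
      meta$img_offset[i] <- lo
      meta$img_scale[i] <- scale
    }
  } else {
    for (i in seq_len(nSamples(dataset))) {
      img <- dataset@images[[i]]
      if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
      RNifti::writeNifti(img,
                         file.path(imgDir, paste0(meta$id[i], ".nii.gz")),
                         datatype = "double")
    }
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset from disk
#'
#' @param dir dataset directory as written by [writeConfoundedDataset()]
#'   (or assembled by hand to the same layout).
#' @param task `"classification"` or `"regression"`.
#' @return a [ConfoundedDataset]. 2-d content stored as single-slice NIfTI
#'   volumes is read back as 2-d arrays; PNG intensities are mapped back
#'   through the recorded rescale.
#' @export
readConfoundedDataset <- function(dir, task = c("classification",
                                                "regression")) {
  task <- match.arg(task)
  metaPath <- file.path(dir, "metadata.csv")
  if (!file.exists(metaPath)) stop("metadata.csv not found in ", dir)
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  if (!all(c("id", "y") %in% names(meta)))
    stop("metadata must contain columns id and y")
  cCols <- grep("^c_[0-9]+$", names(meta), value = TRUE)
  if (!length(cCols)) stop("metadata must contain confounder columns c_1,...")
  imgDir <- file.path(dir, "images")
  images <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$id[i]
    nii <- file.path(imgDir, paste0(id, ".nii.gz"))
    pngf <- file.path(imgDir, paste0(id, ".png"))
    if (file.exists(nii)) {
      img <- as.array(RNifti::readNifti(nii))
      d <- dim(img)
      if (length(d) == 3L && d[3L] == 1L) d <- d[1:2]
      attributes(img) <- NULL
      dim(img) <- d
      images[[i]] <- img
    } else if (file.exists(pngf)) {
      img <- png::readPNG(pngf)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      if (!is.null(meta$img_scale))
        img <- img * meta$img_scale[i] + meta$img_offset[i]
      images[[i]] <- img
    } else {
      stop(sprintf("no image found for id '%s'", id))
    }
  }
  known <- c("id", "y", cCols, "rho", "img_offset", "img_scale")
  extraCols <- setdiff(names(meta), known)
  ds <- ConfoundedDataset(images, meta$y,
                          as.matrix(meta[, cCols, drop = FALSE]),
                          ids = meta$id, task = task,
                          extra = meta[, extraCols, drop = FALSE])
  if (!is.null(meta$rho)) ds@meta$rho <- as.integer(meta$rho)
  ds
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the model, the training configuration and the loss
#' history.
#'
#' @param state a [TrainState].
#' @param config the [TrainingConfig] used.
#' @param path checkpoint file (RDS).
#' @return `saveCheckpoint` the path, invisibly; `loadCheckpoint` a list
#'   with `model`, `config`, `lossHistory`, `iteration`.
#' @export
saveCheckpoint <- function(state, config, path) {
  saveRDS(list(model = state@model, config = config,
               lossHistory = state@lossHistory,
               iteration = state@iteration,
               package_version = as.character(utils::packageVersion("cfnet"))),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
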