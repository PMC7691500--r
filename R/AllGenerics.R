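#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("confounderValues", function(x) standardGeneric("confounderValues"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("confounderNames", function(x) standardGeneric("confounderNames"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("rhoFlags", function(x) standardGeneric("rhoFlags"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("sampleWeights", function(x) standardGeneric("sampleWeights"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("taskType", function(x) standardGeneric("taskType"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("imageShape", function(x) standardGeneric("imageShape"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))

#' @rdname ConfoundedDataset-accessors
#' @export
setGeneric("getSample", function(x, i) standardGeneric("getSample"))
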