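# Accessor generics: slot access stays behind these.

#' Pixel data of an image object
#' @param x a FundusImage or EnhancedImage.
#' @return numeric array (H x W x 3) or matrix (H x W).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname pixels
setMethod("pixels", "FundusImage", function(x) x@pixels)
#' @rdname pixels
setMethod("pixels", "EnhancedImage", function(x) x@pixels)

#' Image identifier
#' @param x a FundusImage.
#' @return character id.
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname imageId
setMethod("imageId", "FundusImage", function(x) x@id)

#' Manifest record table
#' @param x a DatasetManifest.
#' @return data.frame of records.
#' @export
setGeneric("manifestRecords", function(x) standardGeneric("manifestRecords"))
#' @rdname manifestRecords
setMethod("manifestRecords", "DatasetManifest", function(x) x@records)

#' Binary mask matrix
#' @param x a SegmentationMask or SyntheticSample.
#' @return integer H x W matrix.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname maskMatrix
setMethod("maskMatrix", "SegmentationMask", function(x) x@mask)
#' @rdname maskMatrix
setMethod("maskMatrix", "SyntheticSample", function(x) x@mask)

#' Field-of-view mask
#' @param x a SegmentationMask.
#' @return integer H x W matrix.
#' @export
setGeneric("fovMask", function(x) standardGeneric("fovMask"))
#' @rdname fovMask
setMethod("fovMask", "SegmentationMask", function(x) x@fov)

#' Connected components of a mask
#' @param x a SegmentationMask.
#' @return data.frame with label, area and centroid columns.
#' @export
setGeneric("maskComponents", function(x) standardGeneric("maskComponents"))
#' @rdname maskComponents
setMethod("maskComponents", "SegmentationMask", function(x) x@components)

#' Feature value matrix
#' @param x a FeatureSet.
#' @return numeric n x d matrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname featureValues
setMethod("featureValues", "FeatureSet", function(x) x@values)

#' Sample class labels
#' @param x a FeatureSet or SyntheticSample.
#' @return factor (or character) of labels.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname sampleLabels
setMethod("sampleLabels", "FeatureSet", function(x) x@labels)
#' @rdname sampleLabels
setMethod("sampleLabels", "SyntheticSample", function(x) x@label)

#' Selected feature indices
#' @param x a SelectionResult.
#' @return sorted integer vector.
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))
#' @rdname selectedIndices
setMethod("selectedIndices", "SelectionResult", function(x) x@selected)

#' Per-feature importance scores
#' @param x a SelectionResult.
#' @return numeric vector over all features.
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))
#' @rdname featureScores
setMethod("featureScores", "SelectionResult", function(x) x@scores)

#' Fused feature values
#' @param x a FusedVector.
#' @return numeric vector.
#' @export
setGeneric("fusedValues", function(x) standardGeneric("fusedValues"))
#' @rdname fusedValues
setMethod("fusedValues", "FusedVector", function(x) x@values)

#' Training loss trajectory
#' @param x a SegNet.
#' @return numeric vector of per-iteration losses.
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))
#' @rdname lossTrace
setMethod("lossTrace", "SegNet", function(x) x@lossTrace)

#' Posterior probability matrix
#' @param x a ProbabilityMap.
#' @return numeric H x W matrix in [0, 1].
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))
#' @rdname probValues
setMethod("probValues", "ProbabilityMap", function(x) x@probs)

#' Patch-vote coverage counts
#' @param x a ProbabilityMap.
#' @return integer H x W matrix.
#' @export
setGeneric("voteCoverage", function(x) standardGeneric("voteCoverage"))
#' @rdname voteCoverage
setMethod("voteCoverage", "ProbabilityMap", function(x) x@coverage)

#' Model coefficients
#' @param object a MrcevModel.
#' @param ... ignored.
#' @return d x K coefficient matrix.
#' @export
setMethod("coef", "MrcevModel", function(object, ...) object@coef)
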