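# S4 containers for the pipeline's central data objects.

#' FundusImage: a color retinal photograph
#'
#' Pixels are stored as an H x W x 3 array (red, green, blue) with values in
#' [0, 1]; 8-bit sources are divided by 255 at load time.
#'
#' @slot pixels numeric H x W x 3 array in [0, 1].
#' @slot id character image identifier.
#' @slot sourcePath character path the image was read from ("" if in-memory).
#' @export
setClass("FundusImage",
  representation(pixels = "array", id = "character", sourcePath = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 64L || d[2] < 64L) return("image must be at least 64 x 64")
    if (!all(is.finite(object@pixels))) return("pixel values must be finite")
    if (min(object@pixels) < 0 || max(object@pixels) > 1)
      return("pixel values must lie in [0, 1]")
    TRUE
  })

#' Construct a FundusImage
#'
#' @param pixels numeric H x W x 3 array in [0, 1].
#' @param id image identifier.
#' @param sourcePath optional source file path.
#' @return a [FundusImage-class] object.
#' @export
FundusImage <- function(pixels, id = "image", sourcePath = "") {
  new("FundusImage", pixels = pixels, id = as.character(id),
      sourcePath = as.character(sourcePath))
}

#' EnhancedImage: a contrast-enhanced intensity field
#'
#' @slot pixels numeric H x W matrix in [0, 1].
#' @slot params list of the CLAHE parameters used.
#' @export
setClass("EnhancedImage",
  representation(pixels = "matrix", params = "list"),
  validity = function(object) {
    if (!all(is.finite(object@pixels))) return("values must be finite")
    TRUE
  })

#' DatasetManifest: image paths, labels and optional masks
#'
#' @slot records data.frame with columns image_path, label (factor with
#'   levels normal, DR) and mask_path (NA when absent).
#' @slot name character dataset name.
#' @export
setClass("DatasetManifest",
  representation(records = "data.frame", name = "character"),
  validity = function(object) {
    r <- object@records
    need <- c("image_path", "label", "mask_path")
    if (!all(need %in% names(r))) return("records need image_path, label, mask_path")
    if (anyDuplicated(r$image_path)) return("image paths must be unique")
    if (!all(levels(r$label) == c("normal", "DR")))
      return("label must be a factor with levels normal, DR")
    TRUE
  })

#' ProbabilityMap: per-pixel hemorrhage posterior
#'
#' @slot probs numeric H x W matrix of posteriors in [0, 1].
#' @slot coverage integer H x W matrix counting patch votes per pixel.
#' @export
setClass("ProbabilityMap",
  representation(probs = "matrix", coverage = "matrix"),
  validity = function(object) {
    if (!all(dim(object@probs) == dim(object@coverage)))
      return("probs and coverage must share dimensions")
    if (!all(is.finite(object@probs)) || min(object@probs) < 0 ||
        max(object@probs) > 1)
      return("posteriors must be finite in [0, 1]")
    if (any(object@probs[object@coverage == 0] != 0))
      return("pixels with no patch votes must have probability 0")
    TRUE
  })

#' SegmentationMask: a cleaned binary hemorrhage mask
#'
#' @slot mask integer H x W matrix (0 background, 1 hemorrhage).
#' @slot fov integer H x W field-of-view mask.
#' @slot components data.frame of 8-connected components (label, area,
#'   centroid row/col).
#' @export
setClass("SegmentationMask",
  representation(mask = "matrix", fov = "matrix", components = "data.frame"),
  validity = function(object) {
    if (!all(dim(object@mask) == dim(object@fov)))
      return("mask and fov must share dimensions")
    if (any(object@mask != 0 & object@fov == 0))
      return("mask must be contained in the field of view")
    TRUE
  })

#' SyntheticSample: one generated fundus image with ground truth
#'
#' @slot image a [FundusImage-class].
#' @slot mask integer H x W ground-truth hemorrhage mask.
#' @slot label character, "normal" or "DR".
#' @slot provenance list of the per-lesion parameters drawn.
#' @export
setClass("SyntheticSample",
  representation(image = "FundusImage", mask = "matrix", label = "character",
                 provenance = "list"),
  validity = function(object) {
    hasFg <- any(object@mask != 0)
    if (identical(object@label, "DR") != hasFg)
      return("label must be DR exactly when the mask has foreground")
    TRUE
  })

#' SegNet: the patch-based segmentation network
#'
#' Layer stack (fixed): conv 3x3/16 + ReLU, maxpool 2x2 stride 1,
#' conv 3x3/32 + ReLU, conv 3x3/64 + ReLU, maxpool 2x2 stride 2,
#' transposed conv 4x4/64 stride 2 + ReLU, 1x1 conv to 2 class maps,
#' softmax over channels. A 32 x 32 x 3 patch yields a 32 x 32 x 2 score map.
#'
#' @slot layers list of layer descriptors (weights and geometry).
#' @slot inputMean numeric(3) per-channel training mean (zero-center input).
#' @slot trained logical.
#' @slot lossTrace numeric per-iteration training loss.
#' @slot meta list of training metadata (batch size, seed, iterations).
#' @export
setClass("SegNet",
  representation(layers = "list", inputMean = "numeric", trained = "logical",
                 lossTrace = "numeric", meta = "list"))

#' FeatureSet: deep feature vectors with aligned labels
#'
#' @slot values numeric n x d matrix (one row per image).
#' @slot labels factor with levels normal, DR.
#' @slot layer character tag of the source layer (e.g. "fc6", "fc7").
#' @slot ids character image identifiers.
#' @export
setClass("FeatureSet",
  representation(values = "matrix", labels = "factor", layer = "character",
                 ids = "character"),
  validity = function(object) {
    if (nrow(object@values) != length(object@labels))
      return("labels must align with feature rows")
    if (length(object@ids) && length(object@ids) != nrow(object@values))
      return("ids must align with feature rows")
    if (!all(is.finite(object@values))) return("features must be finite")
    TRUE
  })

#' FeatureSet constructor
#'
#' @param values n x d numeric matrix.
#' @param labels factor or character vector of class labels.
#' @param layer source-layer tag.
#' @param ids optional image identifiers.
#' @return a [FeatureSet-class].
#' @export
FeatureSet <- function(values, labels, layer = "fc7", ids = character()) {
  new("FeatureSet", values = as.matrix(values),
      labels = factor(labels, levels = c("normal", "DR")),
      layer = layer, ids = as.character(ids))
}

#' FeatureExtractor: VGG19-style backbone with a 2-class head
#'
#' @slot conv list of conv-layer weights (16 layers in 5 pooled blocks).
#' @slot fc list with fc6, fc7 and head weight/bias pairs.
#' @slot cfg list of configuration (input size, dropout rate, seed).
#' @export
setClass("FeatureExtractor",
  representation(conv = "list", fc = "list", cfg = "list"))

#' MrcevModel: L1-penalised multinomial logistic selection model
#'
#' @slot coef numeric d x K coefficient matrix.
#' @slot intercept numeric K intercepts (unpenalised).
#' @slot regWeight numeric L1 multiplier.
#' @slot classLevels character class labels.
#' @slot probs numeric n x K fitted posteriors.
#' @slot nll numeric negative log-likelihood at the solution.
#' @slot l1Norm numeric sum of absolute coefficients.
#' @slot objective numeric penalised objective at the solution.
#' @slot objTrace numeric objective per accepted iteration.
#' @slot converged logical.
#' @export
setClass("MrcevModel",
  representation(coef = "matrix", intercept = "numeric", regWeight = "numeric",
                 classLevels = "character", probs = "matrix", nll = "numeric",
                 l1Norm = "numeric", objective = "numeric",
                 objTrace = "numeric", converged = "logical"),
  validity = function(object) {
    if (nrow(object@probs) > 0 &&
        max(abs(rowSums(object@probs) - 1)) > 1e-9)
      return("posteriors must sum to 1 per sample")
    if (!is.finite(object@objective)) return("objective must be finite")
    if (object@l1Norm < 0) return("l1 norm must be nonnegative")
    TRUE
  })

#' SelectionResult: ranked feature subset
#'
#' @slot selected integer sorted indices of the retained features.
#' @slot scores numeric per-feature importance (max over classes of |coef|).
#' @slot k integer requested subset size.
#' @export
setClass("SelectionResult",
  representation(selected = "integer", scores = "numeric", k = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@selected)) return("indices must be unique")
    if (length(object@selected) &&
        (min(object@selected) < 1 || max(object@selected) > length(object@scores)))
      return("indices out of range")
    TRUE
  })

#' FusedVector: output of CSID feature fusion
#'
#' @slot values numeric fused vector.
#' @slot sources character tags of the fused inputs.
#' @slot lambda numeric sparsity weight.
#' @slot mode character, "concat" or "sparse".
#' @slot residual numeric reconstruction residual (NA in concat mode).
#' @slot objTrace numeric objective per accepted shrinkage iteration.
#' @slot codes list of sparse code matrices (empty in concat mode).
#' @export
setClass("FusedVector",
  representation(values = "numeric", sources = "character", lambda = "numeric",
                 mode = "character", residual = "numeric",
                 objTrace = "numeric", codes = "list"),
  validity = function(object) {
    if (object@mode == "sparse" && !is.finite(object@residual))
      return("sparse mode must report a finite residual")
    TRUE
  })

#' ElmModel: extreme learning machine with ridge-stabilised output weights
#'
#' @slot inputWeights numeric V x d random input weights, uniform [-1, 1].
#' @slot offsets numeric V hidden offsets.
#' @slot outputWeights numeric V x K solved output weights.
#' @slot penalty numeric penalty parameter x (enters as (1/x) I).
#' @slot hiddenSize integer V.
#' @slot seed integer seed the random layer was drawn from.
#' @slot classLevels character class labels (column order of outputs).
#' @export
setClass("ElmModel",
  representation(inputWeights = "matrix", offsets = "numeric",
                 outputWeights = "matrix", penalty = "numeric",
                 hiddenSize = "integer", seed = "integer",
                 classLevels = "character"),
  validity = function(object) {
    if (object@hiddenSize < 1L) return("hidden size must be >= 1")
    if (object@penalty <= 0) return("penalty must be positive")
    if (!all(is.finite(object@inputWeights)) ||
        !all(is.finite(object@outputWeights)))
      return("weights must be finite")
    TRUE
  })

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage '%s': %d x %d x 3, range [%.3f, %.3f]\n",
              object@id, d[1], d[2], min(object@pixels), max(object@pixels)))
})

setMethod("show", "DatasetManifest", function(object) {
  tab <- table(object@records$label)
  cat(sprintf("DatasetManifest '%s': %d records (normal %d, DR %d)\n",
              object@name, nrow(object@records), tab[["normal"]], tab[["DR"]]))
})

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf("SegmentationMask: %d x %d, %d component(s), %d foreground px\n",
              nrow(object@mask), ncol(object@mask),
              nrow(object@components), sum(object@mask != 0)))
})

setMethod("show", "SegNet", function(object) {
  cat(sprintf("SegNet (32x32x3 -> 32x32x2): %s, %d recorded loss value(s)\n",
              if (object@trained) "trained" else "untrained",
              length(object@lossTrace)))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet [%s]: %d x %d\n", object@layer,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "MrcevModel", function(object) {
  cat(sprintf("MrcevModel: %d features, %d classes, reg %.4g, nnz %d, objective %.6g\n",
              nrow(object@coef), ncol(object@coef), object@regWeight,
              sum(object@coef != 0), object@objective))
})

setMethod("show", "ElmModel", function(object) {
  cat(sprintf("ElmModel: V = %d hidden units, d = %d, penalty %.3g\n",
              object@hiddenSize, ncol(object@inputWeights), object@penalty))
})

setMethod("show", "FeatureExtractor", function(object) {
  cat(sprintf("FeatureExtractor: VGG19-style, %d conv layers, fc6/fc7 4096-d\n",
              length(object@conv)))
})
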