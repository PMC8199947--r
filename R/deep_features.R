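# VGG19-style deep-feature extraction: a 16-conv backbone with 5 max-pools,
# two 4096-unit fully connected layers (fc6, fc7) and a 2-class head used
# for transfer learning. Convolutions run through the same im2col + GEMM
# kernels as the segmentation network.

VGG_PLAN <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                 c(512, 512, 512, 512), c(512, 512, 512, 512))

#' Feature-extractor configuration
#'
#' @param seed integer seed for random weight initialisation.
#' @param weights optional checkpoint directory with pretrained weights
#'   (never required; random seeded weights are the default).
#' @param dropout dropout rate between fully connected layers (default 0.5,
#'   a 50 percent compression ratio; active only while the head trains).
#' @return list of class `extractor_config`.
#' @export
extractorConfig <- function(seed = 1L, weights = NULL, dropout = 0.5) {
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(seed = as.integer(seed), weights = weights,
                 dropout = dropout, inputSize = c(224L, 224L, 3L)),
            class = "extractor_config")
}

#' Build the VGG19-style feature extractor
#'
#' Constructs 16 convolutional layers (widths 64,64 / 128,128 / 256 x 4 /
#' 512 x 4 / 512 x 4, all 3 x 3 pad 1, each block followed by a 2 x 2
#' stride-2 max-pool), fc6 (4096 x 25088 weights + 4096 biases), fc7
#' (4096 x 4096) and a 2-class head. Learnable-parameter counts are
#' asserted at construction: conv1 = 1792, conv2 = 36928, head = 8194.
#'
#' @param cfg an [extractorConfig()].
#' @return a [FeatureExtractor-class].
#' @export
buildExtractor <- function(cfg = extractorConfig()) {
  if (!is.null(cfg$weights)) {
    ck <- loadCheckpoint(cfg$weights)
    ex <- buildExtractorRandom(cfg)
    ex <- loadExtractorWeights(ex, ck$weights)
    return(ex)
  }
  buildExtractorRandom(cfg)
}

buildExtractorRandom <- function(cfg) {
  withSeed(cfg$seed, {
    conv <- list()
    cin <- 3L
    for (bl in seq_along(VGG_PLAN)) {
      for (w in VGG_PLAN[[bl]]) {
        fanIn <- 9L * cin
        conv[[length(conv) + 1L]] <-
          list(W = matrix(rnorm(fanIn * w, 0, sqrt(2 / fanIn)), fanIn, w),
               b = numeric(w), cin = cin, cout = w, block = bl)
        cin <- w
      }
    }
    mkFc <- function(din, dout) {
      W <- rnorm(din * dout, 0, sqrt(2 / din))
      dim(W) <- c(din, dout)  # in-place dim set: avoids an 800 MB copy for fc6
      list(W = W, b = numeric(dout))
    }
    fc <- list(fc6 = mkFc(25088L, 4096L), fc7 = mkFc(4096L, 4096L),
               head = mkFc(4096L, 2L))
    ex <- new("FeatureExtractor", conv = conv, fc = fc, cfg = unclass(cfg))
    pc <- extractorParamCounts(ex)
    stopifnot(pc[["conv1"]] == 1792L, pc[["conv2"]] == 36928L,
              pc[["head"]] == 8194L)
    ex
  })
}

loadExtractorWeights <- function(ex, weights) {
  for (nm in names(weights)) {
    w <- weights[[nm]]
    if (grepl("^conv([0-9]+)_W$", nm)) {
      i <- as.integer(sub("^conv([0-9]+)_W$", "\\1", nm))
      if (!all(dim(ex@conv[[i]]$W) == dim(w)))
        stop(sprintf("weight shape mismatch at %s: have %s, file %s", nm,
                     paste(dim(ex@conv[[i]]$W), collapse = "x"),
                     paste(dim(w), collapse = "x")))
      ex@conv[[i]]$W <- w
    } else if (grepl("^conv([0-9]+)_b$", nm)) {
      i <- as.integer(sub("^conv([0-9]+)_b$", "\\1", nm))
      ex@conv[[i]]$b <- as.numeric(w)
    } else if (nm %in% c("fc6_W", "fc7_W", "head_W")) {
      tag <- sub("_W$", "", nm)
      if (!all(dim(ex@fc[[tag]]$W) == dim(w)))
        stop(sprintf("weight shape mismatch at %s", nm))
      ex@fc[[tag]]$W <- w
    } else if (nm %in% c("fc6_b", "fc7_b", "head_b")) {
      ex@fc[[sub("_b$", "", nm)]]$b <- as.numeric(w)
    }
  }
  ex
}

#' Learnable-parameter counts of the extractor
#'
#' @param ex a [FeatureExtractor-class].
#' @return named integer vector: per-conv-layer counts (`conv1` ...),
#'   `fc6`, `fc7`, `head`, and `total`.
#' @export
extractorParamCounts <- function(ex) {
  out <- integer(0)
  for (i in seq_along(ex@conv)) {
    out[paste0("conv", i)] <- length(ex@conv[[i]]$W) + length(ex@conv[[i]]$b)
  }
  for (nm in names(ex@fc)) {
    out[nm] <- length(ex@fc[[nm]]$W) + length(ex@fc[[nm]]$b)
  }
  out["total"] <- sum(out)
  out
}

# Forward through the frozen conv stack: 224 x 224 x 3 -> 25088 vector.
# Runs in single precision (feature-level accuracy; ~2x throughput); the
# result is still bitwise deterministic across calls.
vggConvForward <- function(ex, roi) {
  d <- dim(roi)
  if (length(d) != 3L || !all(d == c(224L, 224L, 3L)))
    stop("extractor input must be 224 x 224 x 3")
  x <- array(roi, c(224L, 224L, 3L, 1L))
  bl <- 1L
  for (i in seq_along(ex@conv)) {
    ly <- ex@conv[[i]]
    x <- cpp_conv_fwd_f32(x, ly$W, ly$b, 3L, 1L, 1L)
    x <- pmax(x, 0)
    lastInBlock <- i == length(ex@conv) || ex@conv[[min(i + 1L, length(ex@conv))]]$block != ly$block
    if (lastInBlock) x <- cpp_maxpool_fwd(x, 2L, 2L)$y
  }
  as.numeric(x)
}

#' Prepare the 224 x 224 x 3 classifier input from a detection
#'
#' With a non-empty mask: crops the joint bounding box of all hemorrhage
#' components padded by 16 px (clipped to the field-of-view bounding box)
#' and resizes bilinearly to 224 x 224. With an empty mask: resizes the
#' whole field-of-view crop.
#'
#' @param image a [FundusImage-class].
#' @param segMask a [SegmentationMask-class] with matching dimensions.
#' @param pad bounding-box padding in pixels (default 16).
#' @return numeric 224 x 224 x 3 array in [0, 1].
#' @export
prepareRoi <- function(image, segMask, pad = 16L) {
  px <- pixels(image)
  stopifnot(all(dim(px)[1:2] == dim(maskMatrix(segMask))))
  m <- maskMatrix(segMask)
  fov <- fovMask(segMask)
  bbox <- function(b) {
    idx <- which(b != 0)
    if (!length(idx)) return(NULL)
    rows <- (idx - 1L) %% nrow(b) + 1L
    cols <- (idx - 1L) %/% nrow(b) + 1L
    c(min(rows), max(rows), min(cols), max(cols))
  }
  fb <- bbox(fov)
  if (is.null(fb)) fb <- c(1L, nrow(m), 1L, ncol(m))
  bb <- bbox(m)
  if (is.null(bb)) {
    box <- fb
  } else {
    box <- c(max(bb[1] - pad, fb[1]), min(bb[2] + pad, fb[2]),
             max(bb[3] - pad, fb[3]), min(bb[4] + pad, fb[4]))
  }
  crop <- px[box[1]:box[2], box[3]:box[4], , drop = FALSE]
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(crop, colormode = "Color"), w = 224, h = 224))
  clamp01(array(out, c(224L, 224L, 3L)))
}

#' Extract fc6 and fc7 deep-feature vectors
#'
#' Returns post-ReLU activations of the two 4096-unit fully connected
#' layers; dropout is disabled at extraction time, so extraction is
#' deterministic.
#'
#' @param ex a [FeatureExtractor-class].
#' @param roi 224 x 224 x 3 input (from [prepareRoi()]), or a precomputed
#'   25088-long conv-feature vector.
#' @return list with numeric `fc6` and `fc7` vectors, each of length 4096.
#' @export
extractFeatures <- function(ex, roi) {
  cv <- if (is.numeric(roi) && is.null(dim(roi)) && length(roi) == 25088L)
    roi else vggConvForward(ex, roi)
  if (!is.null(ex@fc$convMean)) cv <- cv - ex@fc$convMean
  fc6 <- pmax(as.numeric(cv %*% ex@fc$fc6$W) + ex@fc$fc6$b, 0)
  fc7 <- pmax(as.numeric(fc6 %*% ex@fc$fc7$W) + ex@fc$fc7$b, 0)
  list(fc6 = fc6, fc7 = fc7)
}

#' Class posteriors from the transfer-learning head
#'
#' Forward pass through fc6, fc7 and the 2-class head (dropout off).
#'
#' @param ex a [FeatureExtractor-class].
#' @param convFeatures numeric n x 25088 conv-feature matrix.
#' @return n x 2 matrix of class probabilities (columns normal, DR).
#' @export
headPredict <- function(ex, convFeatures) {
  if (!is.null(ex@fc$convMean))
    convFeatures <- sweep(convFeatures, 2, ex@fc$convMean)
  a6 <- pmax(sweep(convFeatures %*% ex@fc$fc6$W, 2, ex@fc$fc6$b, "+"), 0)
  a7 <- pmax(sweep(a6 %*% ex@fc$fc7$W, 2, ex@fc$fc7$b, "+"), 0)
  P <- softmaxRows(sweep(a7 %*% ex@fc$head$W, 2, ex@fc$head$b, "+"))
  colnames(P) <- c("normal", "DR")
  P
}

#' Fine-tune the fully connected head by transfer learning
#'
#' The convolutional stack stays frozen; fc6, fc7 and the 2-class head are
#' trained by full-batch gradient descent on image-level cross-entropy,
#' with inverted dropout between the fully connected layers. Conv features
#' are zero-centered by their training mean (stored in the extractor and
#' applied at extraction time): with a frozen backbone the common-mode
#' component dominates every input, and removing it is what lets gradient
#' descent see the between-class variance. Deterministic given the seed.
#'
#' @param ex a [FeatureExtractor-class].
#' @param rois list of 224 x 224 x 3 arrays, or `NULL` when
#'   `convFeatures` is supplied.
#' @param labels factor/character labels ("normal"/"DR"), one per sample.
#' @param convFeatures optional precomputed n x 25088 conv-feature matrix
#'   (bypasses the frozen forward passes).
#' @param epochs gradient steps (default 20).
#' @param lr learning rate (default 0.05).
#' @param seed integer seed (dropout masks).
#' @return list with the tuned extractor (`extractor`), the raw
#'   conv-feature matrix (`convFeatures`), and the loss trajectory
#'   (`loss`).
#' @export
finetuneHead <- function(ex, rois = NULL, labels, convFeatures = NULL,
                         epochs = 20L, lr = 0.05, seed = 1L) {
  labels <- factor(labels, levels = c("normal", "DR"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present to fine-tune the head")
  if (is.null(convFeatures)) {
    convFeatures <- t(vapply(rois, function(r) vggConvForward(ex, r),
                             numeric(25088L)))
  }
  n <- nrow(convFeatures)
  stopifnot(n == length(labels))
  convMean <- colMeans(convFeatures)
  convCentered <- sweep(convFeatures, 2, convMean)
  Y <- cbind(normal = labels == "normal", DR = labels == "DR") * 1
  p <- ex@cfg$dropout
  loss <- numeric(epochs)
  # one explicit copy of each weight, then strictly in-place BLAS updates:
  # naive R updates of the 25088 x 4096 fc6 matrix would allocate several
  # ~800 MB temporaries per step
  W6 <- cpp_clone_matrix(ex@fc$fc6$W); b6 <- ex@fc$fc6$b
  W7 <- cpp_clone_matrix(ex@fc$fc7$W); b7 <- ex@fc$fc7$b
  Wh <- cpp_clone_matrix(ex@fc$head$W); bh <- ex@fc$head$b
  withSeed(deriveSeed(seed, 55L), {
    for (it in seq_len(epochs)) {
      a6pre <- sweep(convCentered %*% W6, 2, b6, "+")
      a6 <- pmax(a6pre, 0)
      m6 <- if (p > 0) matrix(rbinom(n * 4096L, 1, 1 - p), n) / (1 - p) else 1
      h6 <- a6 * m6
      a7pre <- sweep(h6 %*% W7, 2, b7, "+")
      a7 <- pmax(a7pre, 0)
      m7 <- if (p > 0) matrix(rbinom(n * 4096L, 1, 1 - p), n) / (1 - p) else 1
      h7 <- a7 * m7
      z <- sweep(h7 %*% Wh, 2, bh, "+")
      P <- softmaxRows(z)
      loss[it] <- -mean(log(rowSums(P * Y) + 1e-12))
      gz <- (P - Y) / n
      g7 <- tcrossprod(gz, Wh) * m7 * (a7pre > 0)
      g6 <- tcrossprod(g7, W7) * m6 * (a6pre > 0)
      cpp_gemm_tn_update(Wh, h7, gz, -lr); bh <- bh - lr * colSums(gz)
      cpp_gemm_tn_update(W7, h6, g7, -lr); b7 <- b7 - lr * colSums(g7)
      cpp_gemm_tn_update(W6, convCentered, g6, -lr)
      b6 <- b6 - lr * colSums(g6)
    }
  })
  ex@fc$fc6 <- list(W = W6, b = b6)
  ex@fc$fc7 <- list(W = W7, b = b7)
  ex@fc$head <- list(W = Wh, b = bh)
  ex@fc$convMean <- convMean
  list(extractor = ex, convFeatures = convFeatures, loss = loss)
}
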