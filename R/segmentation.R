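# Patch-based CNN hemorrhage segmentation: the fixed layer stack, its SGD
# training loop, grid inference with probability-vote averaging, Otsu
# field-of-view estimation, and morphological cleanup.

#' Segmentation training configuration
#'
#' Defaults follow the reference training recipe: batch size 64, learning
#' rate 0.001, 100 epochs, capped at 500 iterations (training stops at
#' `min(epochs * batches, maxIterations)`).
#'
#' @param batchSize minibatch size (default 64).
#' @param learningRate SGD learning rate (default 0.001).
#' @param epochs epoch budget (default 100).
#' @param maxIterations hard iteration cap (default 500).
#' @param seed integer seed (init + shuffling).
#' @param patchesPerImage patches sampled per training image (default 8).
#' @param hemorrhagePatchFraction fraction of training patches centered on
#'   mask-positive pixels (default 0.5).
#' @param momentum SGD momentum coefficient (default 0.9).
#' @param gradClip global L2 gradient-norm ceiling (default 8); steps whose
#'   concatenated gradient exceeds it are rescaled, which tames the large
#'   early steps of the per-patch loss at the fixed learning rate.
#' @return list of class `train_config`.
#' @export
trainConfig <- function(batchSize = 64L, learningRate = 0.001, epochs = 100L,
                        maxIterations = 500L, seed = 1L,
                        patchesPerImage = 8L,
                        hemorrhagePatchFraction = 0.5, momentum = 0.9,
                        gradClip = 8) {
  stopifnot(batchSize >= 1, learningRate > 0, epochs >= 1, maxIterations >= 1,
            patchesPerImage >= 1, hemorrhagePatchFraction >= 0,
            hemorrhagePatchFraction <= 1, momentum >= 0, momentum < 1,
            gradClip > 0)
  structure(list(batchSize = as.integer(batchSize),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 maxIterations = as.integer(maxIterations),
                 seed = as.integer(seed),
                 patchesPerImage = as.integer(patchesPerImage),
                 hemorrhagePatchFraction = hemorrhagePatchFraction,
                 momentum = momentum, gradClip = gradClip),
            class = "train_config")
}

heUniform <- function(fanIn, n) {
  lim <- sqrt(6 / fanIn)
  runif(n, -lim, lim)
}

#' Construct the patch segmentation network
#'
#' Builds the fixed stack (see [SegNet-class]) with seeded He-style uniform
#' initialisation and asserts the output-shape invariant: a 32 x 32 x 3
#' input must produce a 32 x 32 x 2 class-score map.
#'
#' @param seed integer seed for weight initialisation.
#' @return an untrained [SegNet-class].
#' @export
segNet <- function(seed = 1L) {
  mkConv <- function(cin, cout, k) {
    list(type = "conv", k = k, s = 1L, p = as.integer((k - 1) / 2),
         W = matrix(heUniform(k * k * cin, k * k * cin * cout),
                    k * k * cin, cout),
         b = numeric(cout), cin = cin, cout = cout)
  }
  layers <- withSeed(seed, list(
    mkConv(3L, 16L, 3L),
    list(type = "relu"),
    list(type = "pool", size = 2L, stride = 1L),
    mkConv(16L, 32L, 3L),
    list(type = "relu"),
    mkConv(32L, 64L, 3L),
    list(type = "relu"),
    list(type = "pool", size = 2L, stride = 2L),
    list(type = "tconv", k = 4L, s = 2L,
         W = matrix(heUniform(4 * 4 * 64, 4 * 4 * 64 * 64), 4 * 4 * 64, 64),
         b = numeric(64), cin = 64L, cout = 64L),
    list(type = "relu"),
    list(type = "conv", k = 1L, s = 1L, p = 0L,
         W = matrix(heUniform(64, 64 * 2), 64, 2),
         b = numeric(2), cin = 64L, cout = 2L)
  ))
  net <- new("SegNet", layers = layers, inputMean = c(0, 0, 0),
             trained = FALSE, lossTrace = numeric(0),
             meta = list(seed = as.integer(seed)))
  probe <- segForward(net, array(0, c(32, 32, 3, 1)))
  stopifnot(all(dim(probe) == c(32, 32, 2, 1)))
  net
}

#' Forward pass of the segmentation network
#'
#' @param net a [SegNet-class].
#' @param x numeric 32 x 32 x 3 x N batch (an H x W x 3 single patch is
#'   accepted and promoted).
#' @param cache logical; keep intermediates for backpropagation.
#' @return class-score array 32 x 32 x 2 x N (with attribute `cache` when
#'   requested).
#' @export
segForward <- function(net, x, cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] != 3L) stop("patches must have 3 channels")
  for (c in 1:3) x[, , c, ] <- x[, , c, ] - net@inputMean[c]
  states <- if (cache) vector("list", length(net@layers)) else NULL
  for (i in seq_along(net@layers)) {
    ly <- net@layers[[i]]
    if (cache) states[[i]] <- list(input = x)
    if (ly$type == "conv") {
      x <- cpp_conv_fwd(x, ly$W, ly$b, ly$k, ly$s, ly$p)
    } else if (ly$type == "relu") {
      x <- pmax(x, 0)
    } else if (ly$type == "pool") {
      r <- cpp_maxpool_fwd(x, ly$size, ly$stride)
      if (cache) states[[i]]$idx <- r$idx
      x <- r$y
    } else if (ly$type == "tconv") {
      d <- dim(x)
      hOut <- (d[1] - 1L) * ly$s + ly$k
      wOut <- (d[2] - 1L) * ly$s + ly$k
      x <- cpp_conv_bwd_input(x, ly$W, ly$k, ly$s, 0L, hOut, wOut)
      x <- sweep(x, 3, ly$b, "+")
    }
    if (cache) states[[i]]$output <- x
  }
  if (cache) attr(x, "cache") <- states
  x
}

#' Extract training or inference patches
#'
#' In training mode, a seeded sampler centers `hemorrhagePatchFraction` of
#' the patches on mask-positive pixels and the rest on background pixels
#' inside the field of view (warning and all-background fallback when the
#' mask is empty). In grid mode, origins step by `stride` with the final
#' origin clamped so every pixel is covered.
#'
#' @param image numeric H x W x 3 composite (red, enhanced green, blue).
#' @param mask optional ground-truth mask (same H x W).
#' @param n number of training patches (ignored in grid mode).
#' @param hemorrhagePatchFraction fraction of lesion-centered patches.
#' @param fov optional field-of-view mask restricting background centers.
#' @param seed integer seed (training mode).
#' @param mode "train" or "grid".
#' @param stride grid stride in pixels (default 16).
#' @return list of patches, each a list with `pixels`, `labelMap` (or NULL)
#'   and 0-based `origin`.
#' @export
extractPatches <- function(image, mask = NULL, n = 16L,
                           hemorrhagePatchFraction = 0.5, fov = NULL,
                           seed = 1L, mode = c("train", "grid"),
                           stride = 16L) {
  mode <- match.arg(mode)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (H < 32L || W < 32L) stop("image smaller than the 32 x 32 patch size")
  if (!is.null(mask) && !all(dim(mask) == c(H, W)))
    stop("mask/image size mismatch")
  grab <- function(r0, c0) {
    list(pixels = image[(r0 + 1):(r0 + 32), (c0 + 1):(c0 + 32), , drop = FALSE],
         labelMap = if (!is.null(mask))
           mask[(r0 + 1):(r0 + 32), (c0 + 1):(c0 + 32)] else NULL,
         origin = c(r0, c0))
  }
  if (mode == "grid") {
    orgR <- unique(c(seq(0L, H - 32L, by = stride), H - 32L))
    orgC <- unique(c(seq(0L, W - 32L, by = stride), W - 32L))
    out <- vector("list", length(orgR) * length(orgC))
    k <- 1L
    for (c0 in orgC) for (r0 in orgR) {
      out[[k]] <- grab(r0, c0)
      k <- k + 1L
    }
    return(out)
  }
  if (is.null(mask)) stop("training mode needs a ground-truth mask")
  withSeed(seed, {
    nPos <- round(n * hemorrhagePatchFraction)
    posIdx <- which(mask != 0)
    if (!length(posIdx) && nPos > 0) {
      warning("empty mask: falling back to all-background sampling")
      nPos <- 0L
    }
    bgPool <- if (is.null(fov)) which(mask == 0) else which(mask == 0 & fov != 0)
    if (!length(bgPool)) bgPool <- which(mask == 0)
    centers <- c(if (nPos > 0) sample(posIdx, nPos, replace = length(posIdx) < nPos),
                 sample(bgPool, n - nPos, replace = length(bgPool) < (n - nPos)))
    rows <- (centers - 1L) %% H
    cols <- (centers - 1L) %/% H
    r0 <- pmin(pmax(rows - 16L, 0L), H - 32L)
    c0 <- pmin(pmax(cols - 16L, 0L), W - 32L)
    lapply(seq_along(r0), function(i) grab(r0[i], c0[i]))
  })
}

#' Train the segmentation network
#'
#' Minimises mean per-pixel cross-entropy with minibatch SGD (momentum) at
#' the configured learning rate for `min(epochs * batches, maxIterations)`
#' steps. Inputs are zero-centered by the per-channel training mean, which
#' is stored in the network. Deterministic given the seed.
#'
#' @param patches list of labeled patches from [extractPatches()].
#' @param tcfg a [trainConfig()].
#' @return a trained [SegNet-class] with its loss trajectory.
#' @export
trainSegmenter <- function(patches, tcfg = trainConfig()) {
  N <- length(patches)
  if (N < tcfg$batchSize)
    stop("need at least batchSize (", tcfg$batchSize, ") patches, got ", N)
  X <- array(0, c(32, 32, 3, N))
  Y <- array(0L, c(32, 32, N))
  for (i in seq_len(N)) {
    X[, , , i] <- patches[[i]]$pixels
    if (is.null(patches[[i]]$labelMap)) stop("patch ", i, " has no label map")
    Y[, , i] <- patches[[i]]$labelMap
  }
  if (all(Y == 0L) || all(Y != 0L))
    stop("degenerate labels: both pixel classes must be present")
  net <- segNet(seed = tcfg$seed)
  net@inputMean <- c(mean(X[, , 1, ]), mean(X[, , 2, ]), mean(X[, , 3, ]))
  vel <- lapply(net@layers, function(ly)
    if (!is.null(ly$W)) list(W = ly$W * 0, b = ly$b * 0) else NULL)
  nBatches <- N %/% tcfg$batchSize
  totalIter <- min(tcfg$epochs * nBatches, tcfg$maxIterations)
  loss <- numeric(totalIter)
  it <- 0L
  withSeed(deriveSeed(tcfg$seed, 77L), {
    for (ep in seq_len(tcfg$epochs)) {
      if (it >= totalIter) break
      ord <- sample.int(N)
      for (bi in seq_len(nBatches)) {
        if (it >= totalIter) break
        it <- it + 1L
        sel <- ord[((bi - 1L) * tcfg$batchSize + 1L):(bi * tcfg$batchSize)]
        xb <- X[, , , sel, drop = FALSE]
        yb <- Y[, , sel, drop = FALSE]
        logits <- segForward(net, xb, cache = TRUE)
        states <- attr(logits, "cache")
        dmat <- logits[, , 2, ] - logits[, , 1, ]
        pPos <- 1 / (1 + exp(-dmat))
        V <- length(sel)  # per-patch normalization: pixel CE sums within a patch
        eps <- 1e-12
        loss[it] <- -sum(ifelse(yb != 0, log(pPos + eps), log(1 - pPos + eps))) / V
        g <- array(0, dim(logits))
        g[, , 2, ] <- (pPos - (yb != 0)) / V
        g[, , 1, ] <- -g[, , 2, ]
        grads <- segBackward(net, states, g)
        gnorm <- sqrt(sum(vapply(grads, function(x)
          if (is.null(x)) 0 else sum(x$gW^2) + sum(x$gb^2), numeric(1))))
        clipScale <- min(1, tcfg$gradClip / gnorm)
        for (li in seq_along(net@layers)) {
          if (is.null(grads[[li]])) next
          vel[[li]]$W <- tcfg$momentum * vel[[li]]$W -
            tcfg$learningRate * clipScale * grads[[li]]$gW
          vel[[li]]$b <- tcfg$momentum * vel[[li]]$b -
            tcfg$learningRate * clipScale * grads[[li]]$gb
          net@layers[[li]]$W <- net@layers[[li]]$W + vel[[li]]$W
          net@layers[[li]]$b <- net@layers[[li]]$b + vel[[li]]$b
        }
      }
    }
  })
  net@trained <- TRUE
  net@lossTrace <- loss[seq_len(it)]
  net@meta <- list(seed = tcfg$seed, batchSize = tcfg$batchSize,
                   learningRate = tcfg$learningRate, epochs = tcfg$epochs,
                   maxIterations = tcfg$maxIterations, iterationsRun = it,
                   inputMean = net@inputMean)
  net
}

# Backward pass returning weight gradients (conv / tconv layers only).
segBackward <- function(net, states, gOut) {
  grads <- vector("list", length(net@layers))
  g <- gOut
  for (i in rev(seq_along(net@layers))) {
    ly <- net@layers[[i]]
    st <- states[[i]]
    if (ly$type == "conv") {
      gw <- cpp_conv_gradw(st$input, g, ly$k, ly$s, ly$p)
      grads[[i]] <- list(gW = gw$gW, gb = as.numeric(gw$gb))
      din <- dim(st$input)
      g <- cpp_conv_bwd_input(g, ly$W, ly$k, ly$s, ly$p, din[1], din[2])
    } else if (ly$type == "relu") {
      g <- g * (st$output > 0)
    } else if (ly$type == "pool") {
      din <- dim(st$input)
      g <- cpp_maxpool_bwd(g, st$idx, din[1], din[2])
    } else if (ly$type == "tconv") {
      gb <- numeric(ly$cout)
      for (cc in seq_len(ly$cout)) gb[cc] <- sum(g[, , cc, ])
      gw <- cpp_conv_gradw(g, st$input, ly$k, ly$s, 0L)
      grads[[i]] <- list(gW = gw$gW, gb = gb)
      g <- cpp_conv_fwd(g, ly$W, numeric(ly$cin), ly$k, ly$s, 0L)
    }
  }
  grads
}

#' Otsu threshold by inter-class variance maximization
#'
#' Histogram over `levels` equal-width bins; the threshold is the upper
#' edge of the first bin maximizing the between-class variance (cumulative
#' sum formulation; ties on a flat plateau resolve to the lowest
#' threshold).
#'
#' @param v numeric vector or matrix of intensities.
#' @param levels number of histogram bins (default 256).
#' @param range intensity range covered by the histogram.
#' @return the scalar threshold.
#' @export
otsuThreshold <- function(v, levels = 256L, range = c(0, 1)) {
  span <- range[2] - range[1]
  b <- pmin(pmax(floor((as.numeric(v) - range[1]) / span * levels) + 1L, 1L),
            levels)
  h <- tabulate(b, levels)
  mids <- range[1] + (seq_len(levels) - 0.5) * span / levels
  w1 <- cumsum(h)
  m1 <- cumsum(h * mids)
  w2 <- w1[levels] - w1
  m2 <- m1[levels] - m1
  valid <- which(w1 > 0 & w2 > 0)
  if (!length(valid)) stop("degenerate histogram: single occupied bin")
  varb <- (w1 * w2)[valid] * ((m1 / w1)[valid] - (m2 / w2)[valid])^2
  t <- valid[which.max(varb)]
  range[1] + t * span / levels
}

#' Estimate the field of view with Otsu thresholding
#'
#' Thresholds the red channel (where the illuminated retina is brightest
#' against the dark camera surround), keeps the largest 8-connected
#' above-threshold component, and fills its holes.
#'
#' @param image a [FundusImage-class].
#' @return integer H x W FOV mask with attribute `threshold`.
#' @export
otsuFov <- function(image) {
  red <- pixels(image)[, , 1]
  thr <- otsuThreshold(red)
  fg <- red > thr
  if (!any(fg)) stop("empty foreground: no field of view found")
  lab <- cpp_label8(matrix(as.integer(fg), nrow(fg), ncol(fg)))
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  fov <- lab == keep
  fov <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fov * 1))) > 0.5
  out <- matrix(as.integer(fov), nrow(fov), ncol(fov))
  attr(out, "threshold") <- as.numeric(thr)
  out
}

maskComponentsDf <- function(mask) {
  lab <- cpp_label8(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0), area = integer(0),
                      row = numeric(0), col = numeric(0)))
  idx <- which(lab > 0)
  lv <- lab[idx]
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  data.frame(label = seq_len(n),
             area = as.integer(tabulate(lv, n)),
             row = tapply(rows, lv, mean),
             col = tapply(cols, lv, mean), row.names = NULL)
}

#' Morphological cleanup of a binary mask
#'
#' Opening then closing with a disk structuring element, removal of
#' components smaller than `minArea`, and intersection with the field of
#' view.
#'
#' @param mask binary H x W matrix.
#' @param fov binary H x W field-of-view mask.
#' @param radius disk radius of the structuring element (default 2).
#' @param minArea minimum component area in pixels (default 10).
#' @return a [SegmentationMask-class].
#' @export
morphCleanup <- function(mask, fov, radius = 2L, minArea = 10L) {
  stopifnot(all(dim(mask) == dim(fov)))
  m <- (mask != 0) * 1
  if (radius >= 1) {
    kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    m <- EBImage::imageData(EBImage::closing(EBImage::opening(
      EBImage::Image(m), kern), kern))
  }
  m <- (m > 0.5) & (fov != 0)
  lab <- cpp_label8(matrix(as.integer(m), nrow(m), ncol(m)))
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < minArea)
    if (length(drop)) m[lab %in% drop] <- FALSE
  }
  m <- matrix(as.integer(m), nrow(mask), ncol(mask))
  new("SegmentationMask", mask = m, fov = matrix(as.integer(fov != 0),
                                                 nrow(fov), ncol(fov)),
      components = maskComponentsDf(m))
}

#' Predict a hemorrhage mask for a full image
#'
#' Runs grid patches through the network, averages the per-pixel hemorrhage
#' posterior over overlapping patch votes, thresholds strictly at
#' `threshold`, intersects with the field of view, and applies
#' morphological cleanup.
#'
#' @param net a trained [SegNet-class].
#' @param composite numeric H x W x 3 composite (red, enhanced green, blue).
#' @param fov binary field-of-view mask.
#' @param stride patch grid stride (default 16).
#' @param threshold posterior cut (strict >, default 0.5).
#' @param radius cleanup disk radius (default 2).
#' @param minArea minimum component area (default 10).
#' @param batchSize patches per forward batch (default 256).
#' @return list with `prob` (a [ProbabilityMap-class]) and `mask`
#'   (a [SegmentationMask-class]).
#' @export
predictMask <- function(net, composite, fov, stride = 16L, threshold = 0.5,
                        radius = 2L, minArea = 10L, batchSize = 256L) {
  if (!net@trained) stop("network is untrained")
  d <- dim(composite)
  H <- d[1]; W <- d[2]
  patches <- extractPatches(composite, mode = "grid", stride = stride)
  probSum <- matrix(0, H, W)
  cover <- matrix(0L, H, W)
  nP <- length(patches)
  for (s in seq(1L, nP, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, nP)
    xb <- array(0, c(32, 32, 3, length(idx)))
    for (j in seq_along(idx)) xb[, , , j] <- patches[[idx[j]]]$pixels
    logits <- segForward(net, xb)
    pPos <- 1 / (1 + exp(-(logits[, , 2, , drop = FALSE] -
                             logits[, , 1, , drop = FALSE])))
    for (j in seq_along(idx)) {
      o <- patches[[idx[j]]]$origin
      rr <- (o[1] + 1):(o[1] + 32)
      cc <- (o[2] + 1):(o[2] + 32)
      probSum[rr, cc] <- probSum[rr, cc] + pPos[, , 1, j]
      cover[rr, cc] <- cover[rr, cc] + 1L
    }
  }
  probs <- ifelse(cover > 0L, probSum / pmax(cover, 1L), 0)
  raw <- (probs > threshold) & (fov != 0)
  segMask <- morphCleanup(raw, fov, radius = radius, minArea = minArea)
  list(prob = new("ProbabilityMap", probs = probs, coverage = cover),
       mask = segMask)
}
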