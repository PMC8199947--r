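# Green-channel extraction and the modified CLAHE: per-tile clip-limited
# histograms with excess redistribution, a Rayleigh transfer function, linear
# contrast stretching, and bilinear inter-tile interpolation.

#' CLAHE parameters
#'
#' @param tilesX,tilesY tile-grid counts (default 8 x 8).
#' @param nGray number of histogram bins Ngray (default 256).
#' @param nClip normalized clip limit Nclip in [0, 0.01] (default 0.01):
#'   the fraction of a tile's clippable mass added on top of the per-bin
#'   average to form the effective clip limit.
#' @param alpha Rayleigh scale parameter (default 0.4); larger values give a
#'   wider pre-stretch dynamic range, i.e. stronger enhancement.
#' @return a validated parameter list of class `clahe_params`.
#' @export
claheParams <- function(tilesX = 8L, tilesY = 8L, nGray = 256L,
                        nClip = 0.01, alpha = 0.4) {
  if (tilesX < 2L || tilesY < 2L) stop("need at least 2 tiles per axis")
  if (nGray < 2L) stop("nGray must be >= 2")
  if (nClip < 0 || nClip > 0.01) stop("nClip must lie in [0, 0.01]")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(tilesX = as.integer(tilesX), tilesY = as.integer(tilesY),
                 nGray = as.integer(nGray), nClip = nClip, alpha = alpha),
            class = "clahe_params")
}

#' Extract the green channel of a fundus image
#'
#' Hemorrhages and vessels have their highest contrast against the retinal
#' background in the green plane, so all enhancement and segmentation work
#' on this channel.
#'
#' @param image a [FundusImage-class] (or raw H x W x 3 array).
#' @return numeric H x W matrix, the green channel unchanged.
#' @export
extractGreen <- function(image) {
  px <- if (is(image, "FundusImage")) pixels(image) else image
  stopIfNot3Channel(px)
  px[, , 2]
}

# Histogram bin index over [0,1]: nGray equal-width bins, left-closed,
# right-open, top bin closed.
binIndex <- function(v, nGray) {
  pmin(as.integer(floor(v * nGray)) + 1L, nGray)
}

#' Clip a tile histogram and redistribute the excess
#'
#' The per-bin average is Iavg = tile pixels / Ngray. The effective clip
#' limit is `max(1, ceil(Iavg) + round(nClip * (tilePx - ceil(Iavg))))`,
#' the clip-fraction reading of the normalized clip limit (the literal
#' product Nclip * Iavg is also reported for traceability). Clipped mass is
#' first returned uniformly (Nwc / Ngray per bin, capped at the clip limit),
#' then leftover pixels are placed one at a time every
#' `Istep = Ngray / Ncr` bins starting at bin 1, skipping full bins,
#' sweeping until exhausted. Total mass is conserved exactly.
#'
#' @param hist integer per-bin counts.
#' @param params a [claheParams()] list.
#' @param tilePx total pixel count of the tile; must equal `sum(hist)`.
#' @return list with `hist` (clipped counts) and `state` (clip bookkeeping:
#'   iAvg, iClLiteral, iCl, nWc, iAvgGray, iStep, nCr).
#' @export
clipRedistribute <- function(hist, params, tilePx) {
  hist <- as.integer(hist)
  if (sum(hist) != tilePx)
    stop("histogram mass does not match tile pixel count")
  nGray <- params$nGray
  iAvg <- tilePx / nGray
  iClLiteral <- params$nClip * iAvg
  iCl <- max(1L, as.integer(ceiling(iAvg)) +
               as.integer(round(params$nClip * (tilePx - ceiling(iAvg)))))
  clipped <- pmin(hist, iCl)
  nWc <- tilePx - sum(clipped)
  iAvgGray <- nWc / nGray
  share <- as.integer(nWc %/% nGray)
  add <- pmin(share, iCl - clipped)
  clipped <- clipped + add
  nCr <- nWc - sum(add)
  iStep <- if (nCr > 0) max(1L, as.integer(nGray %/% nCr)) else NA_integer_
  rem <- nCr
  while (rem > 0L) {
    step <- max(1L, as.integer(nGray %/% rem))
    b <- 1L
    placedAny <- FALSE
    while (b <= nGray && rem > 0L) {
      if (clipped[b] < iCl) {
        clipped[b] <- clipped[b] + 1L
        rem <- rem - 1L
        placedAny <- TRUE
      }
      b <- b + step
    }
    if (!placedAny) {
      # every visited bin full; capacity argument guarantees free bins exist
      # off the stride, fall back to a dense sweep
      open <- which(clipped < iCl)
      take <- head(open, rem)
      clipped[take] <- clipped[take] + 1L
      rem <- rem - length(take)
      if (!length(take)) stop("internal: no redistribution capacity")
    }
  }
  list(hist = clipped,
       state = list(iAvg = iAvg, iClLiteral = iClLiteral, iCl = iCl,
                    nWc = nWc, iAvgGray = iAvgGray, iStep = iStep, nCr = nCr))
}

#' Build the per-tile Rayleigh transfer function
#'
#' The cumulative probability of the clipped histogram is clamped to
#' 1 - 1e-9 and pushed through the Rayleigh quantile map
#' `Iy = Imin + sqrt(2 alpha^2 ln(1 / (1 - Pin)))`, with `Imin` the
#' intensity of the lowest occupied bin. The Rayleigh output density
#' (`Irox`) is evaluated and reported; the operative per-bin mapping is the
#' linear stretch of `Iy` to [0, 1], which is monotone by construction. A
#' constant tile (single occupied bin) degenerates to the identity mapping.
#'
#' @param hist integer per-bin counts (after clipping and redistribution).
#' @param params a [claheParams()] list.
#' @param support optional integer indices of the bins actually occupied by
#'   tile pixels. Redistribution spreads clipped mass across the whole bin
#'   axis, so the stretch bounds `wMin`/`wMax` are taken over the transfer
#'   values the tile's pixels can reach (default: bins with nonzero counts).
#' @return list of class `clahe_transfer` with `mapping` (per-bin output in
#'   [0,1]), `pIn`, `iMin`, `iY`, `iRox`, `wMin`, `wMax`.
#' @export
rayleighTransfer <- function(hist, params, support = NULL) {
  hist <- as.numeric(hist)
  total <- sum(hist)
  if (total <= 0) stop("zero-mass histogram")
  nGray <- params$nGray
  alpha <- params$alpha
  centers <- (seq_len(nGray) - 0.5) / nGray
  pIn <- pmin(cumsum(hist) / total, 1 - 1e-9)
  if (is.null(support)) support <- which(hist > 0)
  support <- sort(as.integer(support))
  iMin <- (support[1] - 1) / nGray
  z <- sqrt(2 * alpha^2 * log(1 / (1 - pIn)))
  iY <- iMin + z
  iRox <- (iY - iMin) / alpha^2 * exp(-(iY - iMin)^2 / (2 * alpha^2))
  # bins sitting on the finiteness clamp carry a guard value, not a real
  # transfer value; they are excluded from the stretch bounds and saturate
  # to 1 instead
  wBins <- support[pIn[support] < 1 - 2e-9]
  if (length(wBins) < 2L) wBins <- support
  wMin <- min(iY[wBins])
  wMax <- max(iY[wBins])
  mapping <- if (length(support) < 2L || wMax - wMin < 1e-12) {
    centers  # degenerate constant tile: identity
  } else {
    clamp01((iY - wMin) / (wMax - wMin))
  }
  structure(list(mapping = mapping, pIn = pIn, iMin = iMin, iY = iY,
                 iRox = iRox, wMin = wMin, wMax = wMax),
            class = "clahe_transfer")
}

#' Contrast-enhance an intensity field with modified CLAHE
#'
#' The field is partitioned into a `tilesX` x `tilesY` grid (edge tiles
#' absorb remainders); each tile's histogram is clip-limited and converted
#' into a Rayleigh transfer function; every pixel is then mapped by bilinear
#' interpolation between the four surrounding tile-center mappings (one or
#' two mappings at borders), removing tile-boundary artifacts.
#'
#' @param green numeric H x W matrix with values in [0, 1].
#' @param params a [claheParams()] list.
#' @return an [EnhancedImage-class].
#' @export
claheEnhance <- function(green, params = claheParams()) {
  H <- nrow(green); W <- ncol(green)
  ty <- params$tilesY; tx <- params$tilesX
  if (H < ty || W < tx) stop("field smaller than the tile grid")
  if (min(green) < -1e-9 || max(green) > 1 + 1e-9)
    stop("values must lie in [0, 1]")
  green <- clamp01(green)
  nGray <- params$nGray
  B <- matrix(binIndex(green, nGray), H, W)
  rowBreaks <- floor((0:ty) * H / ty)
  colBreaks <- floor((0:tx) * W / tx)
  nTiles <- ty * tx
  Mmap <- matrix(0, nTiles, nGray)
  cy <- numeric(ty); cx <- numeric(tx)
  for (tr in seq_len(ty)) {
    rows <- (rowBreaks[tr] + 1L):rowBreaks[tr + 1L]
    cy[tr] <- (rowBreaks[tr] + rowBreaks[tr + 1L] - 1) / 2
    for (tc in seq_len(tx)) {
      cols <- (colBreaks[tc] + 1L):colBreaks[tc + 1L]
      if (tr == 1L) cx[tc] <- (colBreaks[tc] + colBreaks[tc + 1L] - 1) / 2
      tileBins <- B[rows, cols]
      h <- tabulate(tileBins, nbins = nGray)
      cl <- clipRedistribute(h, params, length(tileBins))
      tf <- rayleighTransfer(cl$hist, params, support = which(h > 0))
      Mmap[(tc - 1L) * ty + tr, ] <- tf$mapping
    }
  }
  interpWeights <- function(pos, centers) {
    n <- length(centers)
    lo <- pmin(pmax(findInterval(pos, centers), 1L), n - 1L)
    hi <- lo + 1L
    w <- (pos - centers[lo]) / (centers[hi] - centers[lo])
    w <- pmin(pmax(w, 0), 1)
    list(lo = lo, hi = hi, w = w)
  }
  ry <- interpWeights(0:(H - 1), cy)
  rx <- interpWeights(0:(W - 1), cx)
  tLo <- rep(rx$lo - 1L, each = H) * ty
  tHi <- rep(rx$hi - 1L, each = H) * ty
  rLo <- rep(ry$lo, W); rHi <- rep(ry$hi, W)
  wy <- rep(ry$w, W); wx <- rep(rx$w, each = H)
  bv <- as.vector(B)
  v11 <- Mmap[cbind(tLo + rLo, bv)]
  v21 <- Mmap[cbind(tLo + rHi, bv)]
  v12 <- Mmap[cbind(tHi + rLo, bv)]
  v22 <- Mmap[cbind(tHi + rHi, bv)]
  out <- (1 - wx) * ((1 - wy) * v11 + wy * v21) +
    wx * ((1 - wy) * v12 + wy * v22)
  new("EnhancedImage", pixels = matrix(clamp01(out), H, W),
      params = unclass(params))
}
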