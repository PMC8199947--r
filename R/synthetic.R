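# Seeded synthetic fundus images with ground-truth hemorrhage masks.
# Emulates the statistical structure of screening photographs: dark camera
# background, circular field of view with a reddish-orange retina and a
# smooth illumination field, a bright optic disc, a dark vessel tree drawn
# as quadratic Bezier strokes (green channel reduced most), and, for DR
# samples, irregular dark-red hemorrhage blobs whose green-channel contrast
# against the background exceeds the red/blue contrast.

#' Synthetic dataset configuration
#'
#' @param size image side length in pixels (default 256).
#' @param nImages number of samples.
#' @param drFraction fraction of DR (hemorrhage-bearing) samples in [0, 1].
#' @param hemorrhageCountRange integer (min, max) lesions per DR image.
#' @param hemorrhageRadiusRange (min, max) lesion radius in pixels.
#' @param hemorrhageContrast green-channel intensity drop inside lesions
#'   (default 0.25); the red channel drops by half this amount.
#' @param vesselCount number of vessel strokes (default 6).
#' @param noiseSd additive Gaussian noise sigma (default 0.02).
#' @param seed integer root seed.
#' @return validated list of class `synthetic_config`.
#' @export
syntheticConfig <- function(size = 256L, nImages = 60L, drFraction = 0.5,
                            hemorrhageCountRange = c(1L, 4L),
                            hemorrhageRadiusRange = c(5, 14),
                            hemorrhageContrast = 0.25,
                            vesselCount = 6L, noiseSd = 0.02, seed = 1L) {
  if (size < 64L) stop("size must be >= 64")
  if (drFraction < 0 || drFraction > 1) stop("drFraction must lie in [0, 1]")
  if (length(hemorrhageCountRange) != 2L ||
      hemorrhageCountRange[1] > hemorrhageCountRange[2])
    stop("hemorrhageCountRange must be (min, max) with min <= max")
  if (length(hemorrhageRadiusRange) != 2L ||
      hemorrhageRadiusRange[1] > hemorrhageRadiusRange[2])
    stop("hemorrhageRadiusRange must be (min, max) with min <= max")
  if (hemorrhageContrast <= 0 || hemorrhageContrast >= 1)
    stop("hemorrhageContrast must lie in (0, 1)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(size = as.integer(size), nImages = as.integer(nImages),
                 drFraction = drFraction,
                 hemorrhageCountRange = as.integer(hemorrhageCountRange),
                 hemorrhageRadiusRange = hemorrhageRadiusRange,
                 hemorrhageContrast = hemorrhageContrast,
                 vesselCount = as.integer(vesselCount),
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Quadratic Bezier stroke rasterised into a logical matrix.
paintStroke <- function(canvas, p0, p1, p2, width) {
  S <- nrow(canvas)
  t <- seq(0, 1, length.out = 4L * S)
  xs <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  ys <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  r <- width / 2
  rr <- ceiling(r)
  offs <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  offs <- offs[offs$dx^2 + offs$dy^2 <= max(r^2, 0.26), , drop = FALSE]
  xi <- round(xs); yi <- round(ys)
  for (k in seq_len(nrow(offs))) {
    px <- xi + offs$dx[k]; py <- yi + offs$dy[k]
    keep <- px >= 1 & px <= S & py >= 1 & py <= S
    canvas[cbind(px[keep], py[keep])] <- TRUE
  }
  canvas
}

# Irregular lesion: union of 1-3 rotated ellipses with angular boundary
# jitter, rasterised over a local window.
paintLesion <- function(mask, center, r0) {
  S <- nrow(mask)
  nell <- sample(1:3, 1)
  win <- ceiling(r0 * 2.2)
  rows <- max(1, round(center[1]) - win):min(S, round(center[1]) + win)
  cols <- max(1, round(center[2]) - win):min(S, round(center[2]) + win)
  X <- outer(rows, rep(1, length(cols))) - center[1]
  Y <- outer(rep(1, length(rows)), cols) - center[2]
  inside <- matrix(FALSE, length(rows), length(cols))
  for (e in seq_len(nell)) {
    off <- if (e == 1) c(0, 0) else runif(2, -r0 / 2, r0 / 2)
    a <- r0 * (if (e == 1) 1 else runif(1, 0.4, 0.8))
    b <- a * runif(1, 0.6, 1)
    th <- runif(1, 0, pi)
    kJ <- sample(3:6, 1); phJ <- runif(1, 0, 2 * pi); aJ <- runif(1, 0.05, 0.15)
    Xe <- X - off[1]; Ye <- Y - off[2]
    Xr <- cos(th) * Xe + sin(th) * Ye
    Yr <- -sin(th) * Xe + cos(th) * Ye
    d <- sqrt((Xr / a)^2 + (Yr / b)^2)
    ang <- atan2(Ye, Xe)
    inside <- inside | (d <= 1 + aJ * sin(kJ * ang + phJ))
  }
  mask[rows, cols] <- mask[rows, cols] | inside
  mask
}

#' Generate one synthetic fundus sample
#'
#' Deterministic per (seed, index). Samples with `index <=
#' round(drFraction * nImages)` carry hemorrhages and are labeled DR; the
#' rest are normal with empty masks. Lesions never overlap the optic disc,
#' and all mask foreground lies inside the circular field of view.
#'
#' @param config a [syntheticConfig()] list.
#' @param index sample index in `1:nImages`.
#' @return a [SyntheticSample-class].
#' @export
generateSample <- function(config, index) {
  stopifnot(is(config, "synthetic_config"))
  S <- config$size
  nDr <- round(config$drFraction * config$nImages)
  isDr <- index <= nDr
  withSeed(deriveSeed(config$seed, 1000L + index), {
    cx <- (S + 1) / 2; cyc <- (S + 1) / 2
    R <- 0.48 * S
    xg <- matrix(seq_len(S), S, S)
    yg <- t(xg)
    distC <- sqrt((xg - cx)^2 + (yg - cyc)^2)
    fov <- distC <= R
    # smooth low-frequency illumination field
    u <- runif(2, 0.5, 1.5) / S; v <- runif(2, 0.5, 1.5) / S
    ph <- runif(2, 0, 2 * pi); am <- runif(2, 0.015, 0.03)
    illum <- am[1] * cos(2 * pi * (u[1] * xg + v[1] * yg) + ph[1]) +
      am[2] * cos(2 * pi * (u[2] * xg - v[2] * yg) + ph[2])
    r <- matrix(0.02, S, S); g <- matrix(0.02, S, S); b <- matrix(0.02, S, S)
    r[fov] <- 0.70 + illum[fov]
    g[fov] <- 0.45 + illum[fov]
    b[fov] <- 0.25 + 0.5 * illum[fov]
    # bright optic disc, fully inside the field of view
    dAng <- runif(1, 0, 2 * pi); dDist <- runif(1, 0.45, 0.68) * R
    dc <- c(cx + dDist * cos(dAng), cyc + dDist * sin(dAng))
    dA <- 0.11 * S / 2; dB <- 0.09 * S / 2
    discMask <- ((xg - dc[1]) / dA)^2 + ((yg - dc[2]) / dB)^2 <= 1
    discMask <- discMask & fov
    r[discMask] <- clamp01(r[discMask] + 0.25)
    g[discMask] <- clamp01(g[discMask] + 0.40)
    b[discMask] <- clamp01(b[discMask] + 0.15)
    # vessel tree: quadratic Bezier strokes from the disc to the FOV rim
    vessel <- matrix(FALSE, S, S)
    for (i in seq_len(config$vesselCount)) {
      ang <- runif(1, 0, 2 * pi)
      end <- c(cx + 0.95 * R * cos(ang), cyc + 0.95 * R * sin(ang))
      mid <- (dc + end) / 2
      perp <- c(-(end - dc)[2], (end - dc)[1])
      perp <- perp / max(sqrt(sum(perp^2)), 1e-9)
      ctrl <- mid + perp * runif(1, -0.2, 0.2) * sqrt(sum((end - dc)^2))
      vessel <- paintStroke(vessel, dc, ctrl, end, width = runif(1, 1, 4))
    }
    vessel <- vessel & fov
    r[vessel] <- r[vessel] - 0.12
    g[vessel] <- g[vessel] - 0.25
    b[vessel] <- b[vessel] - 0.05
    # hemorrhages for DR samples
    mask <- matrix(FALSE, S, S)
    lesions <- list()
    if (isDr) {
      nles <- sample(config$hemorrhageCountRange[1]:config$hemorrhageCountRange[2], 1)
      for (l in seq_len(nles)) {
        for (try in 1:200) {
          r0 <- runif(1, config$hemorrhageRadiusRange[1],
                      config$hemorrhageRadiusRange[2])
          ang <- runif(1, 0, 2 * pi)
          dd <- runif(1, 0, 0.85 * R - r0 * 1.4)
          ctr <- c(cx + dd * cos(ang), cyc + dd * sin(ang))
          distDisc <- sqrt(sum((ctr - dc)^2))
          if (distDisc > dA + r0 * 1.4 + 4) break
        }
        mask <- paintLesion(mask, ctr, r0)
        lesions[[l]] <- list(center = ctr, radius = r0)
      }
      mask <- mask & fov & !discMask
      if (!any(mask)) {  # degenerate fallback: one central round lesion
        mask <- paintLesion(mask, c(cx, cyc), config$hemorrhageRadiusRange[1])
        mask <- mask & fov & !discMask
      }
      r[mask] <- r[mask] - config$hemorrhageContrast / 2
      g[mask] <- g[mask] - config$hemorrhageContrast
    }
    px <- array(0, c(S, S, 3))
    px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
    px <- px + rnorm(length(px), 0, config$noiseSd)
    px <- clamp01(px)
    new("SyntheticSample",
        image = FundusImage(px, id = sprintf("synth_%03d", index)),
        mask = matrix(as.integer(mask), S, S),
        label = if (isDr && any(mask)) "DR" else "normal",
        provenance = list(index = index, seed = config$seed,
                          disc = dc, lesions = lesions))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `nImages` PNG images, PNG ground-truth masks for DR samples, and a
#' manifest CSV (`image_path,label,mask_path`). The DR count equals
#' `round(drFraction * nImages)`.
#'
#' @param config a [syntheticConfig()] list.
#' @param outDir writable output directory (created if absent).
#' @return a [DatasetManifest-class] pointing at the written files.
#' @export
generateDataset <- function(config, outDir) {
  stopifnot(is(config, "synthetic_config"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  outDir <- normalizePath(outDir)  # manifests carry unambiguous paths
  probe <- file.path(outDir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE,
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", outDir)
  unlink(probe)
  rows <- vector("list", config$nImages)
  for (i in seq_len(config$nImages)) {
    smp <- generateSample(config, i)
    imgPath <- file.path(outDir, sprintf("img_%03d.png", i))
    writeFundusPNG(smp@image, imgPath)
    maskPath <- NA_character_
    if (smp@label == "DR") {
      maskPath <- file.path(outDir, sprintf("img_%03d_mask.png", i))
      writeMaskPNG(smp@mask, maskPath)
    }
    rows[[i]] <- data.frame(image_path = imgPath, label = smp@label,
                            mask_path = maskPath, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  records$label <- factor(records$label, levels = c("normal", "DR"))
  manifest <- new("DatasetManifest", records = records, name = "synthetic")
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  manifest
}
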