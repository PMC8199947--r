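# Green-channel extraction and the modified CLAHE: clip/redistribute
# accounting, the Rayleigh transfer, and full-image enhancement.

test_that("extractGreen picks the green plane and rejects non-3-channel input", {
  px <- array(0, c(64, 64, 3))
  px[, , 1] <- 0.7; px[, , 2] <- 0.45; px[, , 3] <- 0.25
  img <- FundusImage(px, "flat")
  expect_equal(extractGreen(img)[1, 1], 0.45)
  allGreen <- array(0, c(64, 64, 3)); allGreen[, , 2] <- 1
  expect_true(all(extractGreen(FundusImage(allGreen, "g")) == 1))
  expect_error(extractGreen(array(0, c(64, 64, 2))), "3")
})

test_that("hemorrhage contrast is largest in the green channel", {
  s <- generateSample(syntheticConfig(size = 256L, nImages = 1L,
                                      drFraction = 1, seed = 7L), 1L)
  px <- pixels(s@image)
  fov <- otsuFov(s@image)
  bg <- fov == 1 & s@mask == 0
  contrast <- vapply(1:3, function(c)
    mean(px[, , c][bg]) - mean(px[, , c][s@mask == 1]), numeric(1))
  expect_gt(contrast[2], contrast[1])
  expect_gt(contrast[2], contrast[3])
})

test_that("clip limits and redistribution conserve mass exactly", {
  p <- claheParams()
  # per-bin average for a 32 x 32 tile with 256 bins
  st <- clipRedistribute(tabulate(rep(1:256, 4), 256), p, 1024L)$state
  expect_equal(st$iAvg, 4)
  # uniform histogram below the clip limit passes through unchanged
  h <- rep(4L, 256)
  r <- clipRedistribute(h, p, 1024L)
  expect_identical(r$hist, h)
  expect_equal(r$state$nWc, 0)
  # delta histogram: mass conserved, excess capped near the clip limit
  hd <- integer(256); hd[100] <- 1024L
  rd <- clipRedistribute(hd, p, 1024L)
  expect_equal(sum(rd$hist), 1024L)
  expect_lte(max(rd$hist), rd$state$iCl + 1L)
  expect_equal(rd$hist[100], rd$state$iCl)
  # mass mismatch is rejected
  expect_error(clipRedistribute(h, p, 1000L), "mass")
})

test_that("mass conservation holds across random histograms", {
  p <- claheParams()
  set.seed(99)
  for (rep in 1:25) {
    tilePx <- sample(c(256L, 1024L, 4096L), 1)
    h <- as.integer(tabulate(sample.int(256, tilePx, replace = TRUE,
                                        prob = runif(256)^3), 256))
    r <- clipRedistribute(h, p, tilePx)
    expect_identical(sum(r$hist), tilePx)
    expect_lte(max(r$hist), r$state$iCl + 1L)
  }
})

test_that("the Rayleigh transfer matches its closed form and stays monotone", {
  p <- claheParams(alpha = 1)
  # a histogram whose cumulative hits 1 - exp(-1/2) at bin 100
  h <- integer(256)
  h[1:100] <- 0L
  total <- 10000L
  h[100] <- round((1 - exp(-0.5)) * total)
  h[200] <- total - h[100]
  tf <- rayleighTransfer(h, p)
  # Iy = Imin + sqrt(2 ln(1/(1-Pin))) = Imin + 1 at the e^{-1/2} bin
  # (tolerance reflects rounding the cumulative to integer counts)
  expect_equal(tf$iY[100] - tf$iMin, 1, tolerance = 1e-3)
  # monotone over bins with nonzero probability
  set.seed(12)
  for (rep in 1:10) {
    hh <- as.integer(tabulate(sample.int(256, 2048, replace = TRUE), 256))
    m <- rayleighTransfer(hh, claheParams())$mapping
    expect_true(all(diff(m[hh > 0]) >= -1e-12))
  }
  expect_error(rayleighTransfer(integer(256), p), "zero-mass")
})

test_that("a constant tile degenerates to the identity mapping", {
  p <- claheParams()
  h <- integer(256); h[130] <- 500L
  tf <- rayleighTransfer(h, p, support = 130L)
  expect_equal(tf$mapping[130], (130 - 0.5) / 256)
})

test_that("larger alpha widens the pre-stretch dynamic range", {
  set.seed(31)
  h <- as.integer(tabulate(sample.int(256, 4096, replace = TRUE,
                                      prob = exp(-(1:256) / 60)), 256))
  spans <- vapply(c(0.2, 0.4, 0.8), function(a) {
    tf <- rayleighTransfer(h, claheParams(alpha = a))
    tf$wMax - tf$wMin
  }, numeric(1))
  expect_true(all(diff(spans) > 0))
})

test_that("claheEnhance stretches low-contrast images and fixes constants", {
  p <- claheParams()
  cst <- claheEnhance(matrix(0.5, 128, 128), p)
  expect_equal(max(pixels(cst)) - min(pixels(cst)), 0)
  expect_equal(pixels(cst)[1, 1], 0.5, tolerance = 1 / 128)

  set.seed(8)
  g <- matrix(runif(256 * 256, 0.4, 0.6), 256)
  e <- pixels(claheEnhance(g, p))
  expect_lte(min(e), 0.05)
  expect_gte(max(e), 0.95)
  gradRms <- function(m) sqrt(mean(diff(m)^2))
  expect_gt(gradRms(e), gradRms(g))
  expect_true(all(e >= 0 & e <= 1))
})

test_that("enhancement commutes with transposition (no cross-tile state)", {
  set.seed(9)
  s <- generateSample(syntheticConfig(size = 128L, nImages = 1L,
                                      drFraction = 1, seed = 9L), 1L)
  g <- extractGreen(s@image)
  p <- claheParams(tilesX = 8L, tilesY = 8L)
  e1 <- pixels(claheEnhance(g, p))
  e2 <- t(pixels(claheEnhance(t(g), p)))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("per-tile rank order of pixel intensities is preserved", {
  set.seed(14)
  g <- matrix(runif(64 * 64), 64)
  p <- claheParams(tilesX = 2L, tilesY = 2L)
  B <- matrix(fundusHem:::binIndex(g, 256L), 64)
  tile <- g[1:32, 1:32]
  h <- tabulate(B[1:32, 1:32], 256)
  cl <- clipRedistribute(h, p, 1024L)
  tf <- rayleighTransfer(cl$hist, p, support = which(h > 0))
  mapped <- tf$mapping[B[1:32, 1:32]]
  ord <- order(tile)
  expect_true(all(diff(mapped[ord]) >= -1e-12))
})

test_that("repeated enhancement contracts toward the target histogram", {
  p <- claheParams()
  for (sd in 1:3) {
    g <- extractGreen(generateSample(syntheticConfig(size = 256L,
                                                     nImages = 1L,
                                                     drFraction = 1,
                                                     seed = sd), 1L)@image)
    gs <- 0.4 + 0.2 * (g - min(g)) / (max(g) - min(g))
    e1 <- pixels(claheEnhance(gs, p))
    e2 <- pixels(claheEnhance(e1, p))
    expect_lt(mean(abs(e2 - e1)), mean(abs(e1 - gs)))
  }
})
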