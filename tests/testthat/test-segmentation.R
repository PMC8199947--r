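# The patch segmentation network: architecture invariants, forward-pass
# oracle equivalence, patch sampling, FOV estimation, and morphology.

test_that("the network maps 32x32x3 to 32x32x2 and softmax normalizes", {
  net <- segNet(seed = 1)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  logits <- segForward(net, x)
  expect_equal(dim(logits), c(32L, 32L, 2L, 2L))
  p1 <- exp(logits[, , 1, ]) / (exp(logits[, , 1, ]) + exp(logits[, , 2, ]))
  p2 <- exp(logits[, , 2, ]) / (exp(logits[, , 1, ]) + exp(logits[, , 2, ]))
  expect_lt(max(abs(p1 + p2 - 1)), 1e-9)
})

test_that("zeroed weights give a uniform posterior of one half", {
  net <- segNet(seed = 1)
  for (i in seq_along(net@layers)) {
    if (!is.null(net@layers[[i]]$W)) {
      net@layers[[i]]$W[] <- 0
      net@layers[[i]]$b[] <- 0
    }
  }
  logits <- segForward(net, array(runif(32 * 32 * 3), c(32, 32, 3)))
  pPos <- 1 / (1 + exp(-(logits[, , 2, 1] - logits[, , 1, 1])))
  expect_true(all(abs(pPos - 0.5) < 1e-12))
})

test_that("convolution agrees with the nested-loop oracle", {
  set.seed(5)
  for (rep in 1:3) {
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    W <- matrix(rnorm(3 * 3 * 2 * 3), 18, 3)
    b <- rnorm(3)
    for (cfgp in list(c(1, 1), c(1, 0), c(2, 0))) {
      got <- fundusHem:::cpp_conv_fwd(x, W, b, 3L, cfgp[1], cfgp[2])
      want <- convOracle(x, W, b, 3, cfgp[1], cfgp[2])
      expect_lt(max(abs(got - want)), 1e-6)
    }
  }
  # constant patch against a single kernel: kernel sum x input + bias
  xc <- array(0.3, c(4, 4, 1, 1))
  W1 <- matrix(rnorm(9), 9, 1); b1 <- 0.7
  got <- fundusHem:::cpp_conv_fwd(xc, W1, b1, 3L, 1L, 0L)
  expect_equal(as.numeric(got), rep(0.3 * sum(W1) + 0.7, 4), tolerance = 1e-12)
})

test_that("grid patch extraction covers the image with documented origins", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ps <- extractPatches(img, mode = "grid", stride = 16L)
  origins <- t(vapply(ps, function(p) p$origin, numeric(2)))
  expect_equal(nrow(origins), 9L)
  expect_setequal(unique(origins[, 1]), c(0, 16, 32))
  expect_setequal(unique(origins[, 2]), c(0, 16, 32))
  # a non-multiple size gets a clamped final origin so coverage is complete
  img2 <- array(runif(70 * 70 * 3), c(70, 70, 3))
  ps2 <- extractPatches(img2, mode = "grid", stride = 16L)
  expect_true(any(vapply(ps2, function(p) p$origin[1], numeric(1)) == 38))
})

test_that("training-mode sampling is seeded and falls back on empty masks", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  mask <- matrix(0L, 64, 64); mask[30:40, 30:40] <- 1L
  a <- extractPatches(img, mask, n = 10, seed = 3, mode = "train")
  b <- extractPatches(img, mask, n = 10, seed = 3, mode = "train")
  expect_identical(lapply(a, `[[`, "origin"), lapply(b, `[[`, "origin"))
  expect_error(extractPatches(img, matrix(0L, 32, 32), mode = "train"),
               "mismatch")
  expect_warning(
    extractPatches(img, matrix(0L, 64, 64), n = 6, seed = 1, mode = "train"),
    "empty mask")
})

test_that("the Otsu threshold equals exhaustive variance maximization", {
  set.seed(17)
  # bimodal, uniform, and fundus-like intensity fields
  fields <- list(
    matrix(c(rnorm(2000, 0.2, 0.05), rnorm(3000, 0.7, 0.08)), 50),
    matrix(runif(2500), 50),
    pixels(generateSample(syntheticConfig(size = 128L, nImages = 1L,
                                          drFraction = 1, seed = 4L),
                          1L)@image)[, , 1])
  for (v in fields) {
    v <- pmin(pmax(v, 0), 1)
    expect_equal(otsuThreshold(v), otsuOracle(v), tolerance = 1e-12)
  }
})

test_that("the estimated field of view matches the generator geometry", {
  s <- generateSample(syntheticConfig(size = 256L, nImages = 1L,
                                      drFraction = 1, seed = 6L), 1L)
  fov <- otsuFov(s@image)
  expect_lt(abs(sum(fov) - pi * (0.48 * 256)^2) / (pi * (0.48 * 256)^2), 0.05)
  dark <- FundusImage(array(0, c(64, 64, 3)), "dark")
  expect_error(otsuFov(dark), "foreground|degenerate")
})

test_that("morphological cleanup removes specks and bridges, keeps solids", {
  fov <- matrix(1L, 64, 64)
  # isolated pixel vanishes under a radius-2 opening
  single <- matrix(0L, 64, 64); single[10, 10] <- 1L
  expect_equal(sum(maskMatrix(morphCleanup(single, fov, radius = 2L,
                                           minArea = 1L))), 0)
  # a solid 20x20 square survives nearly unchanged
  sq <- matrix(0L, 64, 64); sq[20:39, 20:39] <- 1L
  out <- morphCleanup(sq, fov, radius = 2L, minArea = 10L)
  expect_lt(abs(sum(maskMatrix(out)) - 400) / 400, 0.05)
  # two blobs joined by a 1-px bridge come apart
  two <- matrix(0L, 64, 64)
  two[10:20, 10:20] <- 1L; two[10:20, 30:40] <- 1L; two[15, 21:29] <- 1L
  cleaned <- morphCleanup(two, fov, radius = 2L, minArea = 10L)
  expect_equal(nrow(maskComponents(cleaned)), 2L)
  expect_equal(componentCountOracle(maskMatrix(cleaned)), 2L)
  # result is confined to the field of view
  halfFov <- fov; halfFov[, 33:64] <- 0L
  conf <- morphCleanup(sq, halfFov, radius = 2L, minArea = 10L)
  expect_equal(sum(maskMatrix(conf) != 0 & halfFov == 0), 0L)
})

test_that("8-connected labeling agrees with a flood-fill oracle", {
  set.seed(23)
  for (rep in 1:5) {
    m <- matrix(rbinom(30 * 30, 1, 0.25), 30)
    lab <- fundusHem:::cpp_label8(m)
    expect_equal(max(lab), componentCountOracle(m))
  }
})

test_that("an untrained network refuses to predict", {
  net <- segNet(seed = 1)
  comp <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_error(predictMask(net, comp, matrix(1L, 64, 64)), "untrained")
})

test_that("a uniform posterior of exactly one half yields an empty mask", {
  net <- segNet(seed = 1)
  for (i in seq_along(net@layers)) {
    if (!is.null(net@layers[[i]]$W)) {
      net@layers[[i]]$W[] <- 0; net@layers[[i]]$b[] <- 0
    }
  }
  net@trained <- TRUE
  comp <- array(runif(64 * 64 * 3), c(64, 64, 3))
  pr <- predictMask(net, comp, matrix(1L, 64, 64))
  expect_equal(sum(maskMatrix(pr$mask)), 0)
  expect_true(all(voteCoverage(pr$prob) > 0))
})
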