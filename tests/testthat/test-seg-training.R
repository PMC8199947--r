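# Training dynamics and capacity of the patch segmenter on a clearly
# separable fixture (lesion green-drop 0.4). One training run is shared by
# the blocks below (see helper-fixtures.R for the shared extractor).

segFixture <- function() {
  if (!is.null(.fixtures$segTrain)) return(.fixtures$segTrain)
  cfg <- syntheticConfig(size = 256L, nImages = 11L, drFraction = 1,
                         hemorrhageContrast = 0.4, seed = 77L)
  cp <- claheParams()
  prep <- function(i) {
    s <- generateSample(cfg, i)
    comp <- pixels(s@image)
    comp[, , 2] <- pixels(claheEnhance(comp[, , 2], cp))
    list(comp = comp, mask = s@mask, fov = otsuFov(s@image))
  }
  train <- lapply(1:9, prep)
  holdout <- lapply(10:11, prep)
  patches <- list()
  for (j in seq_along(train))
    patches <- c(patches, extractPatches(train[[j]]$comp, train[[j]]$mask,
                                         n = 8, fov = train[[j]]$fov,
                                         seed = j, mode = "train"))
  tc <- trainConfig(epochs = 120L, maxIterations = 120L, seed = 13L)
  net <- trainSegmenter(patches, tc)
  .fixtures$segTrain <- list(net = net, holdout = holdout, tc = tc,
                             nPatches = length(patches))
  .fixtures$segTrain
}

test_that("the loss trajectory is finite and trends downward", {
  fx <- segFixture()
  tr <- lossTrace(fx$net)
  expect_true(all(is.finite(tr)))
  expect_gte(length(tr), 100L)
  ma <- stats::filter(tr, rep(1 / 10, 10), sides = 1)[10:100]
  # 10-step moving average is non-increasing over the first 100 steps,
  # up to minibatch noise (1e-4 of the initial level; a genuine plateau
  # or oscillation shows swings four orders of magnitude larger)
  expect_true(all(diff(ma) <= 1e-4 * ma[1]))
})

test_that("held-out pixel accuracy exceeds 0.9 on the separable fixture", {
  fx <- segFixture()
  for (s in fx$holdout) {
    hp <- extractPatches(s$comp, s$mask, n = 24, fov = s$fov, seed = 5,
                         mode = "train")
    X <- array(0, c(32, 32, 3, 24)); Y <- array(0L, c(32, 32, 24))
    for (i in 1:24) {
      X[, , , i] <- hp[[i]]$pixels
      Y[, , i] <- hp[[i]]$labelMap
    }
    lg <- segForward(fx$net, X)
    pP <- 1 / (1 + exp(-(lg[, , 2, ] - lg[, , 1, ])))
    expect_gte(mean((pP > 0.5) == (Y != 0)), 0.9)
  }
})

test_that("the batch size of 64 is the default and lands in the metadata", {
  fx <- segFixture()
  expect_equal(fx$tc$batchSize, 64L)
  expect_equal(fx$net@meta$batchSize, 64L)
  d <- withr::local_tempdir()
  saveCheckpoint(file.path(d, "ck"), "train-seg", fx$tc$seed, fx$tc,
                 list(w = fx$net@layers[[1]]$W))
  meta <- readLines(file.path(d, "ck", "metadata.txt"))
  expect_true(any(grepl("param_hash", meta)))
  expect_identical(loadCheckpoint(file.path(d, "ck"))$seed, 13L)
})

test_that("training refuses degenerate label sets and tiny patch pools", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  allBg <- replicate(70, list(pixels = img[1:32, 1:32, , drop = FALSE],
                              labelMap = matrix(0L, 32, 32),
                              origin = c(0, 0)), simplify = FALSE)
  expect_error(trainSegmenter(allBg, trainConfig()), "degenerate")
  expect_error(trainSegmenter(allBg[1:10], trainConfig()), "batchSize")
})

test_that("predictions are translation-consistent at one grid stride", {
  fx <- segFixture()
  s <- fx$holdout[[1]]
  full <- predictMask(fx$net, s$comp, s$fov)
  cropComp <- s$comp[17:256, 17:256, , drop = FALSE]
  cropFov <- s$fov[17:256, 17:256]
  crop <- predictMask(fx$net, cropComp, cropFov)
  a <- maskMatrix(full$mask)[17:256, 17:256]
  b <- maskMatrix(crop$mask)
  if (sum(a) + sum(b) > 0)
    expect_gte(diceCoefficient(a, b), 0.95)
})

test_that("a trained net keeps healthy images clean and finds lesions", {
  fx <- segFixture()
  cfgN <- syntheticConfig(size = 256L, nImages = 20L, drFraction = 0,
                          hemorrhageContrast = 0.4, seed = 91L)
  cp <- claheParams()
  emptyCount <- 0L
  for (i in 1:6) {  # a seeded batch of healthy images
    s <- generateSample(cfgN, i)
    comp <- pixels(s@image)
    comp[, , 2] <- pixels(claheEnhance(comp[, , 2], cp))
    pr <- predictMask(fx$net, comp, otsuFov(s@image))
    emptyCount <- emptyCount + (sum(maskMatrix(pr$mask)) == 0)
  }
  expect_gte(emptyCount / 6, 0.9)
  # and the DR holdout images segment well
  dice <- vapply(fx$holdout, function(s)
    diceCoefficient(maskMatrix(predictMask(fx$net, s$comp, s$fov)$mask),
                    s$mask), numeric(1))
  expect_gte(mean(dice), 0.6)
})
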