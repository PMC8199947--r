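# VGG19-style extractor: parameter-count invariants, ROI preparation,
# extraction determinism, and the transfer-learning head. The extractor is
# cached for the duration of this file (released in the final block).

acquireExtractor()

test_that("learnable parameter counts match the architecture", {
  ex <- sharedExtractor()
  pc <- extractorParamCounts(ex)
  expect_identical(unname(pc["conv1"]), 3L * 3L * 3L * 64L + 64L)  # 1792
  expect_identical(unname(pc["conv2"]), 3L * 3L * 64L * 64L + 64L) # 36928
  expect_identical(unname(pc["head"]), 2L * 4096L + 2L)            # 8194
  expect_identical(dim(ex@fc$fc6$W), c(25088L, 4096L))
  expect_identical(length(ex@fc$fc6$b), 4096L)
  expect_identical(dim(ex@fc$fc7$W), c(4096L, 4096L))
  expect_identical(length(ex@conv), 16L)
})

test_that("zero input with zero biases yields zero feature vectors", {
  ex <- sharedExtractor()
  fv <- extractFeatures(ex, numeric(25088L))
  expect_identical(unique(fv$fc6), 0)
  expect_identical(unique(fv$fc7), 0)
})

test_that("feature extraction is 4096-long and bitwise deterministic", {
  ex <- sharedExtractor()
  roi <- array(runif(224 * 224 * 3), c(224, 224, 3))
  f1 <- extractFeatures(ex, roi)
  f2 <- extractFeatures(ex, roi)
  expect_length(f1$fc6, 4096L)
  expect_length(f1$fc7, 4096L)
  expect_identical(f1$fc6, f2$fc6)
  expect_identical(f1$fc7, f2$fc7)
  expect_error(fundusHem:::vggConvForward(ex, array(0, c(100, 100, 3))),
               "224")
})

test_that("ROI preparation follows the bounding-box rules", {
  S <- 256L
  px <- array(0.5, c(S, S, 3))
  img <- FundusImage(px, "roi")
  fov <- matrix(1L, S, S)
  # empty mask: whole field of view, resized
  empty <- new("SegmentationMask", mask = matrix(0L, S, S), fov = fov,
               components = data.frame())
  out <- prepareRoi(img, empty)
  expect_equal(dim(out), c(224L, 224L, 3L))
  # single central 20x20 blob: 52 x 52 crop (20 + 2 x 16) before resizing
  m1 <- matrix(0L, S, S); m1[119:138, 119:138] <- 1L
  seg1 <- new("SegmentationMask", mask = m1, fov = fov,
              components = data.frame())
  marked <- px
  marked[103:154, 103:154, 1] <- 1  # exactly the padded box
  got <- prepareRoi(FundusImage(marked, "m"), seg1)
  expect_equal(dim(got), c(224L, 224L, 3L))
  expect_true(all(got[, , 1] > 0.99))  # crop is exactly the marked region
  # two distant blobs: one joint bounding box covers both
  m2 <- matrix(0L, S, S); m2[20:30, 20:30] <- 1L; m2[200:210, 200:210] <- 1L
  seg2 <- new("SegmentationMask", mask = m2, fov = fov,
              components = data.frame())
  joint <- prepareRoi(img, seg2)
  expect_equal(dim(joint), c(224L, 224L, 3L))
})

test_that("fine-tuning trains only the head and fits separable features", {
  ex <- sharedExtractor()
  set.seed(55)
  n <- 16
  convF <- matrix(abs(rnorm(n * 25088L, 0, 0.05)), n)
  lab <- rep(c("normal", "DR"), each = n / 2)
  convF[lab == "DR", 1:500] <- convF[lab == "DR", 1:500] + 0.5
  convBefore <- lapply(ex@conv, `[[`, "W")
  ft <- finetuneHead(ex, labels = lab, convFeatures = convF,
                     epochs = 25L, lr = 0.05, seed = 9L)
  # conv stack is frozen bit-for-bit
  expect_identical(lapply(ft$extractor@conv, `[[`, "W"), convBefore)
  # loss decreases over the first 20 steps
  expect_lt(mean(ft$loss[16:20]), mean(ft$loss[1:5]))
  expect_true(all(is.finite(ft$loss)))
  # linearly separable fixture is fit exactly
  P <- headPredict(ft$extractor, convF)
  expect_equal(unname(colnames(P)[max.col(P)]), lab)
  expect_error(finetuneHead(ex, labels = rep("DR", 4),
                            convFeatures = convF[1:4, ]), "both classes")
})

test_that("random-weight features keep DR and normal separable (>= 80% LOOCV)", {
  ex <- sharedExtractor()
  cfg <- syntheticConfig(size = 256L, nImages = 16L, drFraction = 0.5,
                         seed = 31L)
  feats <- matrix(0, 16, 4096)
  labs <- character(16)
  for (i in 1:16) {
    s <- generateSample(cfg, i)
    fov <- otsuFov(s@image)
    seg <- new("SegmentationMask", mask = s@mask, fov = fov,
               components = data.frame())
    roi <- prepareRoi(s@image, seg)
    feats[i, ] <- extractFeatures(ex, roi)$fc7
    labs[i] <- s@label
  }
  # leave-one-out nearest-centroid classification
  correct <- 0L
  for (i in 1:16) {
    mu <- vapply(c("normal", "DR"), function(cl)
      colMeans(feats[-i, ][labs[-i] == cl, , drop = FALSE]), numeric(4096))
    dists <- c(sum((feats[i, ] - mu[, 1])^2), sum((feats[i, ] - mu[, 2])^2))
    pred <- c("normal", "DR")[which.min(dists)]
    correct <- correct + (pred == labs[i])
  }
  expect_gte(correct / 16, 0.8)
})

releaseExtractor()
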