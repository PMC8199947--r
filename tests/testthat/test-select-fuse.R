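# MRCEV selection (L1 multinomial logistic) and CSID fusion.

test_that("positiveActivate rectifies elementwise and is idempotent", {
  expect_equal(positiveActivate(c(-1, 0, 2)), c(0, 0, 2))
  m <- matrix(c(-3, -1, -0.5, -2), 2)
  expect_true(all(positiveActivate(m) == 0))
  x <- matrix(rnorm(20), 4)
  expect_identical(positiveActivate(positiveActivate(x)), positiveActivate(x))
})

test_that("a dominant L1 penalty shrinks all coefficients to zero", {
  set.seed(2)
  x <- matrix(rnorm(60 * 5), 60)
  y <- rep(c("normal", "DR"), c(20, 40))
  m <- mrcevFit(x, y, regWeight = 1e6, maxIter = 200)
  expect_true(all(coef(m) == 0))
  # posteriors collapse to the class frequencies
  expect_equal(unname(m@probs[1, ]), c(1 / 3, 2 / 3), tolerance = 1e-3)
})

test_that("the unpenalized fit matches a gradient-descent oracle", {
  set.seed(0)
  n <- 100
  x <- rbind(matrix(rnorm(n / 2 * 2, -2, 0.5), ncol = 2),
             matrix(rnorm(n / 2 * 2, 2, 0.5), ncol = 2))
  y <- rep(c("normal", "DR"), each = n / 2)
  fit <- mrcevFit(x, y, regWeight = 0, maxIter = 2000, tol = 1e-14, seed = 0)
  pred <- apply(fit@probs, 1, which.max)
  truthIdx <- as.integer(factor(y, levels = fit@classLevels))
  expect_equal(mean(pred == truthIdx), 1)
  oracle <- multinomOracle(x, factor(y, levels = c("normal", "DR")),
                           maxIter = 2000)
  expect_lt(abs(fit@objective - oracle$obj), 1e-4)
})

test_that("the proximal objective never increases", {
  set.seed(3)
  x <- matrix(rnorm(80 * 30), 80)
  y <- rep(c("normal", "DR"), 40)
  m <- mrcevFit(x, y, regWeight = 0.05, maxIter = 150)
  expect_true(all(diff(m@objTrace) <= 1e-9))
  expect_lt(max(abs(rowSums(m@probs) - 1)), 1e-9)
})

test_that("planted informative features are recovered in the top 20", {
  set.seed(1)
  n <- 200; d <- 4096
  x <- matrix(rnorm(n * d), n)
  info <- seq_len(20L)
  y <- rep(c("normal", "DR"), each = n / 2)
  x[y == "DR", info] <- x[y == "DR", info] + 1.0
  m <- mrcevFit(x, y, regWeight = 0.01, maxIter = 250, seed = 1)
  sel <- mrcevSelect(m, 20L)
  expect_gte(length(intersect(selectedIndices(sel), info)), 18L)
  expect_true(all(diff(selectedIndices(sel)) > 0))
  # scores of selected dominate the unselected
  sc <- featureScores(sel)
  if (length(selectedIndices(sel)) < d)
    expect_gte(min(sc[selectedIndices(sel)]),
               max(sc[-selectedIndices(sel)]))
})

test_that("sparsity is monotone along the penalty path", {
  set.seed(1)
  n <- 200; d <- 256
  x <- matrix(rnorm(n * d), n)
  y <- rep(c("normal", "DR"), each = n / 2)
  x[y == "DR", 1:10] <- x[y == "DR", 1:10] + 1.0
  nnz <- vapply(c(0.001, 0.01, 0.1, 1), function(dd)
    sum(coef(mrcevFit(x, y, regWeight = dd, maxIter = 200, seed = 1)) != 0),
    numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("selection clamps k, sorts indices, warns on empty models", {
  set.seed(6)
  x <- matrix(rnorm(60 * 12), 60)
  y <- rep(c("normal", "DR"), 30)
  x[y == "DR", 1:3] <- x[y == "DR", 1:3] + 3
  m <- mrcevFit(x, y, regWeight = 0.5, maxIter = 300)
  nz <- sum(apply(abs(coef(m)), 1, max) > 0)
  sel <- mrcevSelect(m, 50L)
  expect_equal(length(selectedIndices(sel)), nz)
  expect_error(mrcevSelect(m, 0L), "positive")
  zm <- mrcevFit(x, y, regWeight = 1e6, maxIter = 50)
  expect_warning(emptySel <- mrcevSelect(zm, 5L), "zero")
  expect_length(selectedIndices(emptySel), 0L)
})

test_that("concat fusion is lossless and ordered", {
  a <- rnorm(500); b <- rnorm(500)
  f <- csidFuse(a, b, mode = "concat")
  expect_length(fusedValues(f), 1000L)
  expect_identical(fusedValues(f)[1:500], a)
  expect_identical(fusedValues(f)[501:1000], b)
})

test_that("sparse fusion descends and collapses under a huge penalty", {
  set.seed(4)
  a <- rnorm(60); b <- rnorm(50)
  f <- csidFuse(a, b, lambda = 0.01, mode = "sparse", seed = 2)
  expect_true(all(diff(f@objTrace) <= 1e-9))
  expect_true(is.finite(f@residual))
  fBig <- csidFuse(a, b, lambda = 1e9, mode = "sparse", seed = 2)
  expect_true(all(unlist(fBig@codes) == 0))
  expect_equal(tail(fBig@objTrace, 1), 0.5 * (sum(a^2) + sum(b^2)),
               tolerance = 1e-9)
  # with a working penalty the data term beats the all-zero solution
  expect_lt(f@residual, 0.5 * (sum(a^2) + sum(b^2)))
  expect_error(csidFuse(a, b, lambda = -1), "nonnegative")
})
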