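# Confusion metrics, ROC/AUC, confidence intervals, replicate averaging.

test_that("confusion counts match hand tallies and a brute-force oracle", {
  cc <- confusionCounts(c("DR", "DR", "normal", "normal"),
                        c("DR", "normal", "normal", "DR"))
  expect_equal(unlist(cc[c("tp", "fn", "tn", "fp")]),
               c(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusionCounts(rep(c("DR", "normal"), c(6, 4)),
                             rep(c("DR", "normal"), c(6, 4)))
  expect_equal(unlist(perfect[c("tp", "tn", "fp", "fn")]),
               c(tp = 6L, tn = 4L, fp = 0L, fn = 0L))
  set.seed(10)
  truth <- sample(c("normal", "DR"), 1000, replace = TRUE)
  pred <- sample(c("normal", "DR"), 1000, replace = TRUE)
  cc2 <- confusionCounts(truth, pred)
  tally <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in seq_len(1000)) {
    key <- if (truth[i] == "DR" && pred[i] == "DR") "tp"
    else if (truth[i] == "normal" && pred[i] == "normal") "tn"
    else if (truth[i] == "normal") "fp" else "fn"
    tally[key] <- tally[key] + 1L
  }
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]), tally)
  expect_error(confusionCounts(c("DR"), c("DR", "DR")), "length")
})

test_that("percentage metrics reproduce the reference detection arithmetic", {
  perfect <- classificationMetrics(list(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(perfect[c("acc", "sn", "sp", "ppv", "f1")]),
               c(acc = 100, sn = 100, sp = 100, ppv = 100, f1 = 100))
  # detection counts: correctly detected DR images over DR test images
  det <- function(correct, total)
    suppressWarnings(classificationMetrics(list(tp = correct, tn = 0, fp = 0,
                                                fn = total - correct)))
  expect_equal(round(det(607, 618)$acc, 2), 98.22)
  expect_equal(round(det(19, 20)$acc, 2), 95.00)
  expect_warning(classificationMetrics(list(tp = 5, tn = 0, fp = 0, fn = 0)),
                 "specificity")
  expect_error(classificationMetrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "all-zero")
})

test_that("label symmetry swaps sensitivity and specificity", {
  set.seed(11)
  truth <- sample(c("normal", "DR"), 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.8, truth,
                 ifelse(truth == "DR", "normal", "DR"))
  m1 <- suppressWarnings(classificationMetrics(confusionCounts(truth, pred)))
  flip <- function(v) ifelse(v == "DR", "normal", "DR")
  m2 <- suppressWarnings(classificationMetrics(confusionCounts(flip(truth),
                                                               flip(pred))))
  expect_equal(m1$sn, m2$sp)
  expect_equal(m1$sp, m2$sn)
  expect_equal(m1$acc, m2$acc)
})

test_that("the ROC sweep matches the U-statistic and its invariances", {
  set.seed(12)
  truth <- sample(c("normal", "DR"), 200, replace = TRUE)
  scores <- rnorm(200) + (truth == "DR") * 0.8
  scores[1:20] <- round(scores[1:20], 1)  # force some ties
  roc <- rocCurve(scores, truth)
  expect_lt(abs(roc$auc - aucOracle(scores, truth)), 1e-12)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(tail(roc$fpr, 1), tail(roc$tpr, 1)), c(1, 1))
  # invariance under strictly monotone transforms
  roc2 <- rocCurve(exp(3 * scores), truth)
  expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)
  # perfectly separated and degenerate-tie cases
  sep <- rocCurve(c(rep(2, 5), rep(1, 5)), rep(c("DR", "normal"), each = 5))
  expect_equal(sep$auc, 1)
  ties <- rocCurve(rep(1, 10), rep(c("DR", "normal"), 5))
  expect_equal(ties$auc, 0.5)
  expect_error(rocCurve(1:5, rep("DR", 5)), "both classes")
})

test_that("Wilson intervals match the closed form; bootstrap handles AUC", {
  ci <- confidenceInterval(1.0, 20)
  expect_equal(round(ci, 3), c(0.839, 1.000))
  # closed-form Wilson cross-check at z = 1.96 quantile
  wilson <- function(x, n) {
    z <- qnorm(0.975); p <- x / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n))
  }
  for (cs in list(c(7, 20), c(19, 20), c(50, 60))) {
    expect_equal(confidenceInterval(cs[1] / cs[2], cs[2]),
                 wilson(cs[1], cs[2]), tolerance = 1e-9)
  }
  # width shrinks with n
  w <- function(n) diff(confidenceInterval(0.5, n))
  expect_lt(w(10000), w(100))
  # bootstrap CI of a perfectly separated AUC is degenerate at 1
  truth <- rep(c("DR", "normal"), each = 10)
  scores <- c(rnorm(10, 5), rnorm(10, -5))
  bci <- confidenceInterval(NA, NA, "bootstrap", scores = scores,
                            truth = truth, nBoot = 200, seed = 2)
  expect_equal(bci, c(1, 1))
})

test_that("replicate averaging reports means, CIs, and failures honestly", {
  fixed <- function(seed) c(acc = 90, sn = 80)
  rep1 <- replicateAndAverage(fixed, nReplicates = 10, rootSeed = 1)
  expect_equal(unname(rep1$mean["acc"]), 90)
  expect_equal(rep1$ci95$acc, c(90, 90))
  expect_false(rep1$incomplete)
  expect_equal(nrow(rep1$perReplicate), 10L)

  noisy <- function(seed) withSeed(seed, c(acc = 90 + rnorm(1)))
  rep2 <- replicateAndAverage(noisy, nReplicates = 10, rootSeed = 3)
  expect_equal(unname(rep2$mean["acc"]),
               mean(rep2$perReplicate$acc), tolerance = 1e-12)
  # a replicate that fails is recorded and flags the report
  flaky <- function(seed) if (seed %% 2 == 0) stop("boom") else c(acc = 1)
  rep3 <- replicateAndAverage(flaky, nReplicates = 4, rootSeed = 0)
  expect_true(rep3$incomplete)
  expect_equal(rep3$nSucceeded, 2L)
  expect_length(rep3$failures, 2L)
})
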