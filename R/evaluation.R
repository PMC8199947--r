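# Evaluation battery: confusion counts, percentage metrics, ROC/AUC,
# confidence intervals, and replicate averaging. DR is the positive class
# throughout.

#' Confusion counts for a two-class detection task
#'
#' @param truth,pred vectors of labels in {normal, DR}; DR is positive.
#' @return list of class `confusion_counts` with tp, tn, fp, fn.
#' @export
confusionCounts <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and prediction lengths differ")
  truth <- as.character(truth); pred <- as.character(pred)
  if (!all(c(truth, pred) %in% c("normal", "DR")))
    stop("labels must be 'normal' or 'DR'")
  structure(list(tp = sum(truth == "DR" & pred == "DR"),
                 tn = sum(truth == "normal" & pred == "normal"),
                 fp = sum(truth == "normal" & pred == "DR"),
                 fn = sum(truth == "DR" & pred == "normal")),
            class = "confusion_counts")
}

#' Percentage metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity and positive predictive value as
#' percentages, and F1 (also scaled to percent) from precision and recall.
#' Ratios with zero denominators are reported as NA with a warning.
#'
#' @param counts a `confusion_counts` list (or anything with tp/tn/fp/fn).
#' @return list of class `hem_metrics` with acc, sn, sp, ppv, f1.
#' @export
classificationMetrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("all-zero confusion counts")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    100 * num / den
  }
  acc <- 100 * (tp + tn) / total
  sn <- ratio(tp, tp + fn, "sensitivity")
  sp <- ratio(tn, tn + fp, "specificity")
  ppv <- ratio(tp, tp + fp, "positive predictive value")
  f1 <- if (is.na(sn) || is.na(ppv) || (sn + ppv) == 0) NA_real_
        else 2 * ppv * sn / (ppv + sn)
  structure(list(acc = acc, sn = sn, sp = sp, ppv = ppv, f1 = f1,
                 counts = counts),
            class = "hem_metrics")
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps descending unique score thresholds (equal scores grouped), so the
#' curve runs from (0, 0) to (1, 1); AUC is the trapezoidal area and equals
#' the Mann-Whitney U statistic over positive/negative pairs.
#'
#' @param scores numeric positive-class (DR) scores.
#' @param truth labels in {normal, DR}; both classes must be present.
#' @return list of class `roc_curve` with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
rocCurve <- function(scores, truth) {
  truth <- as.character(truth)
  if (!all(is.finite(scores))) stop("scores must be finite")
  pos <- truth == "DR"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tpByGrp <- tapply(p, grp, sum)
  fpByGrp <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tpByGrp) / nP)
  fpr <- c(0, cumsum(fpByGrp) / nN)
  thresholds <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, fpr = as.numeric(fpr),
                 tpr = as.numeric(tpr), auc = auc),
            class = "roc_curve")
}

#' Confidence interval for a proportion or a bootstrapped AUC
#'
#' Proportions get the 95 percent Wilson score interval; with
#' `method = "bootstrap"` the interval comes from seeded resampling of
#' (score, label) pairs and is meant for the AUC.
#'
#' @param point proportion in [0, 1] (ignored for bootstrap).
#' @param n sample count behind the proportion.
#' @param method "wilson" or "bootstrap".
#' @param scores,truth score/label vectors (bootstrap only).
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed integer seed (bootstrap only).
#' @return numeric (low, high).
#' @export
confidenceInterval <- function(point, n, method = c("wilson", "bootstrap"),
                               scores = NULL, truth = NULL, nBoot = 2000L,
                               seed = 1L) {
  method <- match.arg(method)
  if (method == "wilson") {
    if (n < 1) stop("n must be >= 1")
    if (point < 0 || point > 1) stop("point must lie in [0, 1]")
    x <- round(point * n)
    ci <- suppressWarnings(prop.test(x, n, correct = FALSE)$conf.int)
    return(as.numeric(ci))
  }
  stopifnot(!is.null(scores), !is.null(truth))
  truth <- as.character(truth)
  idxP <- which(truth == "DR"); idxN <- which(truth == "normal")
  if (!length(idxP) || !length(idxN)) stop("both classes must be present")
  vals <- withSeed(seed, vapply(seq_len(nBoot), function(i) {
    take <- c(sample(idxP, length(idxP), replace = TRUE),
              sample(idxN, length(idxN), replace = TRUE))
    rocCurve(scores[take], truth[take])$auc
  }, numeric(1)))
  as.numeric(quantile(vals, c(0.025, 0.975), names = FALSE, type = 7))
}

#' Run an experiment across seeded replicates and average the metrics
#'
#' Calls `experiment(seed)` for seeds `rootSeed + 1 ... rootSeed + n`; the
#' callable must return a named numeric vector of metrics. Reports the
#' per-replicate values, their means, and across-replicate 95 percent
#' t-intervals. Failed replicates are recorded and the report is marked
#' incomplete when fewer than `nReplicates` succeed.
#'
#' @param experiment function(seed) -> named numeric vector.
#' @param nReplicates number of replicates (default 10).
#' @param rootSeed integer root seed.
#' @return list of class `replicate_report`.
#' @export
replicateAndAverage <- function(experiment, nReplicates = 10L, rootSeed = 1L) {
  rows <- list(); fails <- list()
  for (i in seq_len(nReplicates)) {
    sd_i <- rootSeed + i
    res <- tryCatch(experiment(sd_i), error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- list(seed = sd_i,
                                          message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- c(seed = sd_i, res)
    }
  }
  if (!length(rows)) stop("every replicate failed")
  tab <- do.call(rbind, rows)
  metricCols <- setdiff(colnames(tab), "seed")
  means <- colMeans(tab[, metricCols, drop = FALSE])
  nOk <- nrow(tab)
  ci <- lapply(metricCols, function(cn) {
    v <- tab[, cn]
    if (nOk < 2L || sd(v) == 0) return(c(means[[cn]], means[[cn]]))
    half <- qt(0.975, nOk - 1L) * sd(v) / sqrt(nOk)
    c(means[[cn]] - half, means[[cn]] + half)
  })
  names(ci) <- metricCols
  structure(list(perReplicate = as.data.frame(tab), mean = means, ci95 = ci,
                 nRequested = nReplicates, nSucceeded = nOk,
                 failures = fails, incomplete = nOk < nReplicates),
            class = "replicate_report")
}
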