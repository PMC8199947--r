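# Eight-stage pipeline orchestration: synthetic data or manifest in,
# metrics report out. All randomness fans out from one root seed by fixed
# per-stage offsets, so identical configs give byte-identical reports.

#' Default pipeline configuration
#'
#' Study conditions for the synthetic benchmark: 60 images of side 256,
#' half DR, lesion green-contrast 0.25, 55:45 stratified split, the reference
#' training recipe for the segmenter (batch 64, lr 0.001, 100 epochs,
#' 500-iteration cap).
#'
#' @param outDir output directory.
#' @param seed root seed.
#' @param nImages synthetic sample count (default 60).
#' @param size image side (default 256).
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(outDir = tempfile("hemrun"), seed = 1L,
                                  nImages = 60L, size = 256L) {
  list(
    seed = as.integer(seed),
    out_dir = outDir,
    synthetic = list(n_images = as.integer(nImages), size = as.integer(size),
                     dr_fraction = 0.5, hemorrhage_contrast = 0.25,
                     hemorrhage_count_range = c(1L, 4L),
                     hemorrhage_radius_range = c(5, 14),
                     vessel_count = 6L, noise_sd = 0.02),
    split = list(train_fraction = 0.55),
    preprocess = list(tiles_x = 8L, tiles_y = 8L, n_gray = 256L,
                      n_clip = 0.01, alpha = 0.4),
    segmentation = list(patches_per_image = 8L,
                        hemorrhage_patch_fraction = 0.5,
                        batch_size = 64L, learning_rate = 0.001,
                        epochs = 100L, max_iterations = 500L,
                        momentum = 0.9, grad_clip = 8, stride = 16L,
                        threshold = 0.5, disk_radius = 2L, min_area = 10L),
    features = list(finetune_epochs = 20L, finetune_lr = 0.05,
                    dropout = 0.5, weights = NULL),
    select = list(reg = 0.01, k = 1000L),
    fuse = list(mode = "concat", lambda = 0.01),
    elm = list(hidden = 500L, penalty = 1.0),
    evaluate = list(bootstrap_auc = FALSE),
    output = list(write_images = TRUE)
  )
}

readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("preprocess", "segmentation", "features", "select", "fuse",
                "elm", "evaluate")
  for (sec in required) {
    if (is.null(config[[sec]]))
      stop(sprintf("pipeline config is missing the '%s' section", sec))
  }
  if (is.null(config$synthetic) && is.null(config$manifest))
    stop("pipeline config needs a 'synthetic' block or a 'manifest' path")
  if (is.null(config$out_dir)) stop("pipeline config needs 'out_dir'")
  if (is.null(config$seed)) config$seed <- 1L
  config
}

stageRun <- function(stage, logCon, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

logLine <- function(con, ...) {
  writeLines(sprintf(...), con)
  flush(con)
}

#' Run the full hemorrhage-detection pipeline
#'
#' Executes the fixed stage order: green channel, CLAHE enhancement,
#' segmenter training + inference, deep-feature extraction with head
#' fine-tuning, MRCEV selection, CSID fusion, ELM classification, and
#' evaluation. Per-stage artifacts (enhanced images, masks, probability
#' maps, feature matrices, checkpoints), a metrics report (JSON + text) and
#' a run log recording every seed and parameter are written under
#' `out_dir`.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or a
#'   YAML file path.
#' @return the report list, invisibly; also written to
#'   `out_dir/report.json`.
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  root <- as.integer(cfg$seed)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- file(file.path(out, "runlog.txt"), "w")
  on.exit(close(log), add = TRUE)
  logLine(log, "run started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logLine(log, "root seed: %d", root)
  logLine(log, "config: %s", paste(deparse(cfg), collapse = " "))

  # --- data -----------------------------------------------------------
  manifest <- stageRun("data", log, {
    if (!is.null(cfg$synthetic)) {
      sc <- cfg$synthetic
      scfg <- syntheticConfig(
        size = sc$size %||% 256L, nImages = sc$n_images %||% 60L,
        drFraction = sc$dr_fraction %||% 0.5,
        hemorrhageCountRange = sc$hemorrhage_count_range %||% c(1L, 4L),
        hemorrhageRadiusRange = sc$hemorrhage_radius_range %||% c(5, 14),
        hemorrhageContrast = sc$hemorrhage_contrast %||% 0.25,
        vesselCount = sc$vessel_count %||% 6L,
        noiseSd = sc$noise_sd %||% 0.02,
        seed = deriveSeed(root, 1L))
      logLine(log, "stage data: synthetic n=%d size=%d seed=%d",
              scfg$nImages, scfg$size, scfg$seed)
      generateDataset(scfg, file.path(out, "data"))
    } else {
      logLine(log, "stage data: manifest %s", cfg$manifest)
      loadManifest(cfg$manifest)
    }
  })
  records <- manifestRecords(manifest)
  n <- nrow(records)

  split <- stageRun("split", log, {
    sp <- splitSpec(cfg$split$train_fraction %||% 0.55, deriveSeed(root, 2L))
    logLine(log, "stage split: fraction=%.3f seed=%d", sp$trainFraction, sp$seed)
    splitTrainTest(manifest, sp)
  })
  trainPaths <- manifestRecords(split$train)$image_path
  isTrain <- records$image_path %in% trainPaths

  # --- preprocess -----------------------------------------------------
  pp <- cfg$preprocess
  cp <- claheParams(tilesX = pp$tiles_x %||% 8L, tilesY = pp$tiles_y %||% 8L,
                    nGray = pp$n_gray %||% 256L, nClip = pp$n_clip %||% 0.01,
                    alpha = pp$alpha %||% 0.4)
  writeImages <- isTRUE(cfg$output$write_images %||% TRUE)
  if (writeImages) {
    dir.create(file.path(out, "enhanced"), showWarnings = FALSE)
    dir.create(file.path(out, "masks"), showWarnings = FALSE)
    dir.create(file.path(out, "probs"), showWarnings = FALSE)
  }
  images <- vector("list", n)
  enhanced <- vector("list", n)
  fovs <- vector("list", n)
  composites <- vector("list", n)
  stageRun("preprocess", log, {
    for (i in seq_len(n)) {
      id <- basename(records$image_path[i])
      img <- tryCatch(readFundus(records$image_path[i]),
                      error = function(e) stop(id, ": ", conditionMessage(e)))
      g <- extractGreen(img)
      enh <- claheEnhance(g, cp)
      comp <- pixels(img)
      comp[, , 2] <- pixels(enh)
      images[[i]] <- img
      enhanced[[i]] <- enh
      composites[[i]] <- comp
      fovs[[i]] <- otsuFov(img)
      if (writeImages)
        writeEnhancedPNG(enh, file.path(out, "enhanced", paste0(imageId(img), "_enh.png")))
    }
    logLine(log, "stage preprocess: %d images, tiles %dx%d nclip %.4f alpha %.2f",
            n, cp$tilesX, cp$tilesY, cp$nClip, cp$alpha)
  })

  # --- segmentation ---------------------------------------------------
  sg <- cfg$segmentation
  segSeed <- deriveSeed(root, 4L)
  net <- stageRun("segment-train", log, {
    drTrain <- which(isTrain & records$label == "DR" & !is.na(records$mask_path))
    if (!length(drTrain)) stop("no DR training images with masks")
    ppi <- sg$patches_per_image %||% 8L
    bs <- sg$batch_size %||% 64L
    if (ppi * length(drTrain) < bs)
      ppi <- as.integer(ceiling(bs / length(drTrain)))
    patches <- list()
    for (i in drTrain) {
      gt <- readMaskPNG(records$mask_path[i])
      patches <- c(patches, extractPatches(
        composites[[i]], mask = gt, n = ppi,
        hemorrhagePatchFraction = sg$hemorrhage_patch_fraction %||% 0.5,
        fov = fovs[[i]], seed = deriveSeed(segSeed, i), mode = "train"))
    }
    tc <- trainConfig(batchSize = bs, learningRate = sg$learning_rate %||% 0.001,
                      epochs = sg$epochs %||% 100L,
                      maxIterations = sg$max_iterations %||% 500L,
                      seed = segSeed, patchesPerImage = ppi,
                      hemorrhagePatchFraction = sg$hemorrhage_patch_fraction %||% 0.5,
                      momentum = sg$momentum %||% 0.9,
                      gradClip = sg$grad_clip %||% 8)
    logLine(log, "stage segment-train: %d patches from %d images, seed=%d",
            length(patches), length(drTrain), segSeed)
    netT <- trainSegmenter(patches, tc)
    saveCheckpoint(file.path(out, "checkpoints", "segnet"), "segment-train",
                   segSeed, tc,
                   stats::setNames(
                     lapply(which(!vapply(netT@layers, function(l) is.null(l$W), TRUE)),
                            function(li) netT@layers[[li]]$W),
                     paste0("layer", which(!vapply(netT@layers, function(l) is.null(l$W), TRUE)), "_W")))
    logLine(log, "stage segment-train: %d iterations, final loss %.5f",
            netT@meta$iterationsRun, tail(netT@lossTrace, 1))
    netT
  })

  segMasks <- vector("list", n)
  stageRun("segment", log, {
    for (i in seq_len(n)) {
      pr <- predictMask(net, composites[[i]], fovs[[i]],
                        stride = sg$stride %||% 16L,
                        threshold = sg$threshold %||% 0.5,
                        radius = sg$disk_radius %||% 2L,
                        minArea = sg$min_area %||% 10L)
      segMasks[[i]] <- pr$mask
      if (writeImages) {
        id <- imageId(images[[i]])
        writeMaskPNG(maskMatrix(pr$mask), file.path(out, "masks", paste0(id, "_mask.png")))
        writeEnhancedPNG(probValues(pr$prob), file.path(out, "probs", paste0(id, "_prob.png")))
      }
    }
    logLine(log, "stage segment: %d images, stride %d threshold %.2f",
            n, sg$stride %||% 16L, sg$threshold %||% 0.5)
  })

  # --- deep features --------------------------------------------------
  ft <- cfg$features
  featSeed <- deriveSeed(root, 5L)
  feats <- stageRun("features", log, {
    ex <- buildExtractor(extractorConfig(seed = featSeed,
                                         weights = ft$weights,
                                         dropout = ft$dropout %||% 0.5))
    convF <- matrix(0, n, 25088L)
    for (i in seq_len(n)) {
      roi <- prepareRoi(images[[i]], segMasks[[i]])
      convF[i, ] <- vggConvForward(ex, roi)
    }
    tuned <- finetuneHead(ex, labels = records$label[isTrain],
                          convFeatures = convF[isTrain, , drop = FALSE],
                          epochs = ft$finetune_epochs %||% 20L,
                          lr = ft$finetune_lr %||% 0.05, seed = featSeed)
    ex <- NULL  # release the untuned fc6 copy before extraction
    gc(verbose = FALSE)
    logLine(log, "stage features: seed=%d finetune epochs=%d final loss %.5f",
            featSeed, ft$finetune_epochs %||% 20L, tail(tuned$loss, 1))
    fc6 <- matrix(0, n, 4096L); fc7 <- matrix(0, n, 4096L)
    for (i in seq_len(n)) {
      fv <- extractFeatures(tuned$extractor, convF[i, ])
      fc6[i, ] <- fv$fc6; fc7[i, ] <- fv$fc7
    }
    ids <- vapply(images, imageId, character(1))
    list(fc6 = FeatureSet(fc6, records$label, layer = "fc6", ids = ids),
         fc7 = FeatureSet(fc7, records$label, layer = "fc7", ids = ids))
  })
  dir.create(file.path(out, "features"), showWarnings = FALSE)
  writeFeatureCSV(feats$fc6, file.path(out, "features", "fc6.csv"))
  writeFeatureCSV(feats$fc7, file.path(out, "features", "fc7.csv"))

  # --- selection ------------------------------------------------------
  selSeed <- deriveSeed(root, 6L)
  sel <- stageRun("select", log, {
    k <- cfg$select$k %||% 1000L
    reg <- cfg$select$reg %||% 0.01
    pick <- function(fs) {
      act <- positiveActivate(featureValues(fs))
      model <- mrcevFit(act[isTrain, , drop = FALSE],
                        sampleLabels(fs)[isTrain], regWeight = reg,
                        seed = selSeed)
      res <- mrcevSelect(model, k)
      list(model = model, sel = res)
    }
    s6 <- pick(feats$fc6); s7 <- pick(feats$fc7)
    logLine(log, "stage select: reg=%.4g k=%d kept fc6=%d fc7=%d seed=%d",
            reg, k, length(selectedIndices(s6$sel)),
            length(selectedIndices(s7$sel)), selSeed)
    list(fc6 = s6, fc7 = s7)
  })

  # --- fusion ---------------------------------------------------------
  fused <- stageRun("fuse", log, {
    i6 <- selectedIndices(sel$fc6$sel)
    i7 <- selectedIndices(sel$fc7$sel)
    if (!length(i6) || !length(i7))
      stop("empty selection: nothing to fuse")
    a <- positiveActivate(featureValues(feats$fc6))[, i6, drop = FALSE]
    b <- positiveActivate(featureValues(feats$fc7))[, i7, drop = FALSE]
    mode <- cfg$fuse$mode %||% "concat"
    rows <- lapply(seq_len(n), function(i)
      fusedValues(csidFuse(a[i, ], b[i, ], lambda = cfg$fuse$lambda %||% 0.01,
                           mode = mode, seed = deriveSeed(root, 600L + i))))
    logLine(log, "stage fuse: mode=%s dim=%d", mode, length(rows[[1]]))
    do.call(rbind, rows)
  })

  # --- ELM ------------------------------------------------------------
  elmSeed <- deriveSeed(root, 7L)
  elm <- stageRun("elm", log, {
    m <- elmTrain(fused[isTrain, , drop = FALSE], records$label[isTrain],
                  hiddenSize = cfg$elm$hidden %||% 500L,
                  penalty = cfg$elm$penalty %||% 1.0, seed = elmSeed)
    saveCheckpoint(file.path(out, "checkpoints", "elm"), "train-elm", elmSeed,
                   cfg$elm, list(input_W = m@inputWeights,
                                 offsets = m@offsets,
                                 output_W = m@outputWeights))
    logLine(log, "stage elm: V=%d penalty=%.3g seed=%d",
            m@hiddenSize, m@penalty, elmSeed)
    m
  })

  # --- evaluation -----------------------------------------------------
  report <- stageRun("evaluate", log, {
    testIdx <- which(!isTrain)
    predTest <- elmPredict(elm, fused[testIdx, , drop = FALSE])
    truthTest <- as.character(records$label[testIdx])
    counts <- confusionCounts(truthTest, as.character(predTest$predicted))
    mets <- suppressWarnings(classificationMetrics(counts))
    roc <- rocCurve(predTest$positiveScore, truthTest)
    nTest <- length(testIdx)
    wils <- function(p, n) if (is.na(p) || n == 0) c(NA_real_, NA_real_)
      else confidenceInterval(p / 100, n)
    ci <- list(acc = wils(mets$acc, nTest),
               sn = wils(mets$sn, counts$tp + counts$fn),
               sp = wils(mets$sp, counts$tn + counts$fp),
               ppv = wils(mets$ppv, counts$tp + counts$fp))
    ci$auc <- if (isTRUE(cfg$evaluate$bootstrap_auc))
      confidenceInterval(NA, NA, "bootstrap", scores = predTest$positiveScore,
                         truth = truthTest, seed = deriveSeed(root, 8L))
      else c(NA_real_, NA_real_)
    # segmentation quality on the held-out split
    dice <- numeric(0)
    emptyOnNormal <- logical(0)
    for (i in testIdx) {
      if (records$label[i] == "DR" && !is.na(records$mask_path[i])) {
        gt <- readMaskPNG(records$mask_path[i])
        dice <- c(dice, diceCoefficient(maskMatrix(segMasks[[i]]), gt))
      } else if (records$label[i] == "normal") {
        emptyOnNormal <- c(emptyOnNormal, sum(maskMatrix(segMasks[[i]])) == 0)
      }
    }
    list(
      n_images = n, n_train = sum(isTrain), n_test = nTest,
      confusion = list(tp = counts$tp, tn = counts$tn, fp = counts$fp,
                       fn = counts$fn),
      metrics_pct = list(acc = mets$acc, sn = mets$sn, sp = mets$sp,
                         ppv = mets$ppv, f1 = mets$f1, auc = 100 * roc$auc),
      ci95 = ci,
      segmentation = list(mean_dice_test_dr = if (length(dice)) mean(dice) else NA_real_,
                          dice_per_image = dice,
                          healthy_empty_mask_rate = if (length(emptyOnNormal))
                            mean(emptyOnNormal) else NA_real_),
      seeds = list(root = root, data = deriveSeed(root, 1L),
                   split = deriveSeed(root, 2L), segmentation = segSeed,
                   features = featSeed, select = selSeed, elm = elmSeed),
      params = cfg[c("split", "preprocess", "segmentation", "features",
                     "select", "fuse", "elm")]
    )
  })
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(
    "hemorrhage detection report",
    sprintf("images: %d (train %d / test %d)", report$n_images,
            report$n_train, report$n_test),
    sprintf("confusion (test): TP %d TN %d FP %d FN %d",
            report$confusion$tp, report$confusion$tn, report$confusion$fp,
            report$confusion$fn),
    sprintf("Acc %.2f%%  Sn %.2f%%  Sp %.2f%%  PPV %.2f%%  F1 %.2f  AUC %.2f%%",
            report$metrics_pct$acc, report$metrics_pct$sn,
            report$metrics_pct$sp, report$metrics_pct$ppv,
            report$metrics_pct$f1, report$metrics_pct$auc),
    sprintf("mean Dice (test DR): %.3f",
            report$segmentation$mean_dice_test_dr),
    sprintf("healthy empty-mask rate: %.3f",
            report$segmentation$healthy_empty_mask_rate))
  writeLines(txt, file.path(out, "report.txt"))
  logLine(log, "run finished")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
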