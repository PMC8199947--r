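# Reading and writing the pipeline's file formats: images, binary masks,
# dataset manifests, feature matrices, and checkpoint directories.

#' Read a fundus image from PNG/JPEG/TIFF
#'
#' 8-bit (or 16-bit) intensities are rescaled to [0, 1]; an alpha channel,
#' if present, is dropped.
#'
#' @param path image file path.
#' @param id identifier (defaults to the file name without extension).
#' @return a [FundusImage-class].
#' @export
readFundus <- function(path, id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L)
    stop("expected a 3-channel color image: ", path)
  if (dim(px)[3] > 3L) px <- px[, , 1:3]
  px <- clamp01(px)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  FundusImage(px, id = id, sourcePath = path)
}

#' Write a fundus image as PNG
#' @param image a [FundusImage-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFundusPNG <- function(image, path) {
  EBImage::writeImage(EBImage::Image(pixels(image), colormode = "Color"),
                      path, type = "png")
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask binary H x W matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  EBImage::writeImage(EBImage::Image((mask != 0) * 1), path, type = "png")
  invisible(path)
}

#' Read a binary mask PNG
#' @param path mask file path.
#' @return integer H x W matrix of 0/1.
#' @export
readMaskPNG <- function(path) {
  px <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(px)) == 3L) px <- px[, , 1]
  matrix(as.integer(px > 0.5), nrow(px), ncol(px))
}

#' Write an enhanced intensity field as an 8-bit PNG
#' @param enhanced an [EnhancedImage-class] (or H x W matrix).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnhancedPNG <- function(enhanced, path) {
  px <- if (is(enhanced, "EnhancedImage")) pixels(enhanced) else enhanced
  EBImage::writeImage(EBImage::Image(clamp01(px)), path, type = "png")
  invisible(path)
}

#' Load a dataset manifest CSV
#'
#' The CSV must carry a header `image_path,label[,mask_path]`; labels must
#' be `normal` or `DR`; relative paths are resolved against the CSV's
#' directory.
#'
#' @param path manifest CSV path.
#' @param name dataset name (defaults to the file name).
#' @return a [DatasetManifest-class].
#' @export
loadManifest <- function(path, name = NULL) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "label") %in% names(df)))
    stop("manifest needs columns image_path and label")
  if (!"mask_path" %in% names(df)) df$mask_path <- NA_character_
  df$mask_path[!is.na(df$mask_path) & df$mask_path == ""] <- NA_character_
  bad <- which(!df$label %in% c("normal", "DR"))
  if (length(bad))
    stop(sprintf("unknown label '%s' in manifest row %d (expected 'normal' or 'DR')",
                 df$label[bad[1]], bad[1] + 1L))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p), p,
           file.path(base, p))
  }
  df$image_path <- resolve(df$image_path)
  df$mask_path <- resolve(df$mask_path)
  df$label <- factor(df$label, levels = c("normal", "DR"))
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  new("DatasetManifest", records = df[c("image_path", "label", "mask_path")],
      name = name)
}

#' Write a dataset manifest CSV
#' @param manifest a [DatasetManifest-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  df <- manifestRecords(manifest)
  df$label <- as.character(df$label)
  df$mask_path[is.na(df$mask_path)] <- ""
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Train/test split specification
#'
#' @param trainFraction fraction of records assigned to training
#'   (default 0.55, the 55:45 train:test strategy).
#' @param seed integer seed for the stratified shuffle.
#' @return list of class `split_spec`.
#' @export
splitSpec <- function(trainFraction = 0.55, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  structure(list(trainFraction = trainFraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split of a manifest
#'
#' Splits stratified by image-level label with a seeded shuffle. The total
#' training size is `round(trainFraction * n)`; per-class counts are the
#' largest-remainder apportionment of that total, so each class deviates
#' from the target fraction by at most one record.
#'
#' @param manifest a [DatasetManifest-class] with both classes present.
#' @param spec a [splitSpec()].
#' @return list with `train` and `test` manifests.
#' @export
splitTrainTest <- function(manifest, spec = splitSpec()) {
  df <- manifestRecords(manifest)
  if (!nrow(df)) stop("manifest is empty")
  counts <- table(df$label)
  if (any(counts == 0))
    stop("cannot stratify: both classes must be present")
  if (any(counts < 2))
    stop("cannot stratify: every class needs at least 2 members")
  nTrainTotal <- round(spec$trainFraction * nrow(df))
  frac <- spec$trainFraction * as.numeric(counts)
  nc <- floor(frac)
  extra <- nTrainTotal - sum(nc)
  if (extra > 0) {
    ord <- order(-(frac - nc), seq_along(nc))
    nc[ord[seq_len(extra)]] <- nc[ord[seq_len(extra)]] + 1L
  } else if (extra < 0) {
    ord <- order(frac - nc, seq_along(nc))
    nc[ord[seq_len(-extra)]] <- nc[ord[seq_len(-extra)]] - 1L
  }
  trainIdx <- integer(0)
  withSeed(spec$seed, {
    for (k in seq_along(counts)) {
      idx <- which(as.integer(df$label) == k)
      idx <- idx[sample.int(length(idx))]
      trainIdx <- c(trainIdx, idx[seq_len(nc[k])])
    }
  })
  trainIdx <- sort(trainIdx)
  mk <- function(rows, tag) new("DatasetManifest",
                                records = df[rows, , drop = FALSE],
                                name = paste0(manifest@name, ".", tag))
  list(train = mk(trainIdx, "train"),
       test = mk(setdiff(seq_len(nrow(df)), trainIdx), "test"))
}

#' Write a feature matrix as CSV
#'
#' Columns: `id`, `label`, then one column per feature index.
#'
#' @param fs a [FeatureSet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFeatureCSV <- function(fs, path) {
  vals <- featureValues(fs)
  df <- data.frame(id = if (length(fs@ids)) fs@ids else seq_len(nrow(vals)),
                   label = as.character(sampleLabels(fs)),
                   stringsAsFactors = FALSE)
  m <- as.data.frame(vals)
  names(m) <- as.character(seq_len(ncol(vals)))
  out <- cbind(df, m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  for (i in seq_len(nrow(out))) {
    writeLines(paste(c(out$id[i], out$label[i],
                       sprintf("%.17g", vals[i, ])), collapse = ","), con)
  }
  invisible(path)
}

#' Read a feature matrix CSV written by [writeFeatureCSV()]
#' @param path CSV path.
#' @param layer layer tag to attach.
#' @return a [FeatureSet-class].
#' @export
readFeatureCSV <- function(path, layer = "fc7") {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(vals) <- NULL
  FeatureSet(vals, df$label, layer = layer, ids = as.character(df$id))
}

#' Save a checkpoint directory
#'
#' A checkpoint is a directory holding a plain-text `metadata.txt` (stage,
#' seed, parameter hash, blob inventory) and one binary blob per weight
#' array, giving inspectable provenance.
#'
#' @param dir checkpoint directory (created if needed).
#' @param stage stage name.
#' @param seed integer seed the stage ran under.
#' @param params list of stage parameters (hashed into the metadata).
#' @param weights named list of numeric arrays.
#' @return the directory, invisibly.
#' @export
saveCheckpoint <- function(dir, stage, seed, params, weights) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(sprintf("stage: %s", stage),
            sprintf("seed: %d", as.integer(seed)),
            sprintf("param_hash: %s", paramHash(params)),
            sprintf("n_blobs: %d", length(weights)))
  for (nm in names(weights)) {
    w <- weights[[nm]]
    d <- if (is.null(dim(w))) length(w) else dim(w)
    writeBin(as.numeric(w), file.path(dir, paste0(nm, ".bin")), size = 8)
    meta <- c(meta, sprintf("blob: %s dims: %s", nm, paste(d, collapse = "x")))
  }
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Load a checkpoint directory saved by [saveCheckpoint()]
#' @param dir checkpoint directory.
#' @return list with `stage`, `seed`, `paramHash` and named `weights`.
#' @export
loadCheckpoint <- function(dir) {
  metaPath <- file.path(dir, "metadata.txt")
  if (!file.exists(metaPath)) stop("not a checkpoint directory: ", dir)
  meta <- readLines(metaPath)
  getv <- function(key) sub(paste0("^", key, ": "), "",
                            grep(paste0("^", key, ": "), meta, value = TRUE))
  blobs <- grep("^blob: ", meta, value = TRUE)
  weights <- list()
  for (b in blobs) {
    parts <- strsplit(sub("^blob: ", "", b), " dims: ")[[1]]
    nm <- parts[1]
    d <- as.integer(strsplit(parts[2], "x")[[1]])
    v <- readBin(file.path(dir, paste0(nm, ".bin")), what = "numeric",
                 n = prod(d), size = 8)
    if (length(d) > 1L) dim(v) <- d
    weights[[nm]] <- v
  }
  list(stage = getv("stage"), seed = as.integer(getv("seed")),
       paramHash = getv("param_hash"), weights = weights)
}
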