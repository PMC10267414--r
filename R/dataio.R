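# Reading and writing image + palette-mask pairs, the augmentation pipeline
# (shared geometric transform for image and mask, photometric transforms for
# the image only), center crop / zero pad, and k-fold split construction.

#' Default annotation palette
#'
#' The eight retinal layer colors used by the annotation masks, in layer
#' order NFL, GCL+IPL, INL, OPL, ONL, ELM+IS, OS, RPE (red, brown, yellow,
#' dark green, light green, light blue, dark blue, pink), with class 0 the
#' black background.
#'
#' @return A [ClassPalette-class] with 9 classes.
#' @export
defaultPalette <- function() {
  new("ClassPalette",
      colors = matrix(as.integer(c(
        0, 0, 0,        # background
        255, 0, 0,      # NFL - red
        139, 69, 19,    # GCL+IPL - brown
        255, 255, 0,    # INL - yellow
        0, 100, 0,      # OPL - dark green
        144, 238, 144,  # ONL - light green
        173, 216, 230,  # ELM+IS - light blue
        0, 0, 139,      # OS - dark blue
        255, 192, 203   # RPE - pink
      )), ncol = 3, byrow = TRUE),
      labels = c("background", "NFL", "GCL+IPL", "INL", "OPL", "ONL",
                 "ELM+IS", "OS", "RPE"))
}

.rgbTo255 <- function(rgb) {
  if (length(dim(rgb)) == 3L && dim(rgb)[3L] >= 3L) rgb <- rgb[, , 1:3]
  else stop("expected an H x W x 3 RGB array")
  if (max(rgb) <= 1) rgb <- rgb * 255
  round(rgb)
}

#' Decode a palette mask to class labels
#'
#' Maps each RGB pixel to its class index by exact palette match (no
#' nearest-color snapping: a color outside the palette signals a corrupt
#' mask and raises an error naming the color and the pixel).
#'
#' @param rgb `H x W x 3` array, values in \[0,1\] or \[0,255\].
#' @param palette A [ClassPalette-class].
#' @return Integer `H x W` matrix of labels, 0-based.
#' @export
decodeMask <- function(rgb, palette = defaultPalette()) {
  rgb <- .rgbTo255(rgb)
  H <- dim(rgb)[1L]; W <- dim(rgb)[2L]
  key <- rgb[, , 1L] * 65536 + rgb[, , 2L] * 256 + rgb[, , 3L]
  palKey <- drop(palette@colors %*% c(65536, 256, 1))
  lab <- match(as.numeric(key), palKey)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1L]
    r <- (bad - 1L) %% H + 1L
    cc <- (bad - 1L) %/% H + 1L
    stop(sprintf("unknown mask color (%d, %d, %d) at pixel (%d, %d)",
                 rgb[r, cc, 1L], rgb[r, cc, 2L], rgb[r, cc, 3L], r, cc))
  }
  matrix(as.integer(lab) - 1L, H, W)
}

#' Encode class labels as a palette mask
#'
#' Inverse of [decodeMask()]: `encodeMask(decodeMask(x)) == x` pixel for
#' pixel.
#'
#' @param mask Integer `H x W` label matrix.
#' @param palette A [ClassPalette-class].
#' @return `H x W x 3` RGB array with values in \[0,1\].
#' @export
encodeMask <- function(mask, palette = defaultPalette()) {
  if (min(mask) < 0 || max(mask) >= nrow(palette@colors))
    stop("mask labels exceed the palette")
  H <- nrow(mask); W <- ncol(mask)
  out <- array(0, c(H, W, 3L))
  for (ch in 1:3)
    out[, , ch] <- matrix(palette@colors[mask + 1L, ch] / 255, H, W)
  out
}

#' Augmentation configuration
#'
#' Parameters of the stochastic training augmentations: horizontal flip,
#' random rotation, Gaussian blur and multiplicative contrast adjustment.
#' Geometric transforms are applied identically to image and mask (mask with
#' nearest-neighbour interpolation); blur and contrast touch the image only.
#'
#' @param hflipProbability Probability of a horizontal flip, in \[0,1\].
#' @param rotationRange Rotation drawn uniformly from
#'   `[-rotationRange, rotationRange]` degrees.
#' @param blurSigmaRange Two-element interval of the Gaussian blur sigma in
#'   pixels; `c(0, 0)` disables blur.
#' @param contrastRange Two-element interval of the multiplicative contrast
#'   factor; `c(1, 1)` disables it.
#' @return A list of class `"augmentationConfig"`.
#' @export
augmentationConfig <- function(hflipProbability = 0.5, rotationRange = 10,
                               blurSigmaRange = c(0, 1.5),
                               contrastRange = c(0.9, 1.1)) {
  if (hflipProbability < 0 || hflipProbability > 1)
    stop("hflipProbability must lie in [0, 1]")
  if (rotationRange < 0) stop("rotationRange must be >= 0")
  if (length(blurSigmaRange) != 2L || diff(blurSigmaRange) < 0 || blurSigmaRange[1L] < 0)
    stop("blurSigmaRange must be a well-ordered non-negative interval")
  if (length(contrastRange) != 2L || diff(contrastRange) < 0 || contrastRange[1L] <= 0)
    stop("contrastRange must be a well-ordered positive interval")
  structure(list(hflipProbability = hflipProbability,
                 rotationRange = rotationRange,
                 blurSigmaRange = blurSigmaRange,
                 contrastRange = contrastRange),
            class = "augmentationConfig")
}

#' @rdname augmentationConfig
#' @details `identityAugmentation()` is the configuration under which
#'   [augmentSample()] is the identity map.
#' @export
identityAugmentation <- function() {
  augmentationConfig(hflipProbability = 0, rotationRange = 0,
                     blurSigmaRange = c(0, 0), contrastRange = c(1, 1))
}

# Rotation by inverse affine mapping about the image centre; `filter` is
# "bilinear" for the image and "nearest" for the mask.  Exposed corners are
# filled with `fill` (background 0).
rotateGrid <- function(m, angleDeg, filter = c("bilinear", "nearest"), fill = 0) {
  filter <- match.arg(filter)
  H <- nrow(m); W <- ncol(m)
  th <- angleDeg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- rep.int(seq_len(H), W) - cy
  cc <- rep(seq_len(W), each = H) - cx
  # inverse rotation: source coordinates that land on each output pixel
  sr <- cos(th) * r + sin(th) * cc + cy
  sc <- -sin(th) * r + cos(th) * cc + cx
  out <- rep(fill, H * W)
  if (filter == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- m[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- m[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      m[i10] * fr[ok] * (1 - fc[ok]) +
      m[i01] * (1 - fr[ok]) * fc[ok] +
      m[i11] * fr[ok] * fc[ok]
  }
  matrix(out, H, W)
}

gaussianBlur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(seq(-half, half), sd = sigma)
  K <- outer(g, g)
  K <- K / sum(K)
  EBImage::filter2(img, K, boundary = "replicate")
}

#' Apply training augmentations to an annotated scan
#'
#' Draws the augmentation parameters deterministically from `rngSeed` and
#' applies: horizontal flip and rotation to image and mask alike (mask with
#' nearest-neighbour interpolation, exposed corners filled with background
#' 0), then Gaussian blur and contrast scaling to the image only.  The
#' output label set is always a subset of the input labels plus background.
#'
#' @param sample An [AnnotatedBScan-class].
#' @param config An [augmentationConfig()].
#' @param rngSeed Integer seed; the same seed reproduces the same transform.
#' @return The augmented [AnnotatedBScan-class].
#' @export
augmentSample <- function(sample, config = augmentationConfig(), rngSeed = 1L) {
  stopifnot(is(sample, "AnnotatedBScan"), inherits(config, "augmentationConfig"))
  set.seed(rngSeed)
  doFlip <- stats::runif(1) < config$hflipProbability
  angle <- if (config$rotationRange > 0)
    stats::runif(1, -config$rotationRange, config$rotationRange) else 0
  sigma <- stats::runif(1, config$blurSigmaRange[1L], config$blurSigmaRange[2L])
  factor <- stats::runif(1, config$contrastRange[1L], config$contrastRange[2L])

  img <- sample@image
  mask <- sample@mask
  if (doFlip) {
    img <- img[, ncol(img):1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (angle != 0) {
    img <- rotateGrid(img, angle, "bilinear", fill = 0)
    mask <- rotateGrid(mask, angle, "nearest", fill = 0L)
  }
  if (sigma > 1e-3) img <- gaussianBlur(img, sigma)
  if (factor != 1) img <- img * factor
  img <- pmin(pmax(img, 0), 1)
  AnnotatedBScan(image = img, mask = mask)
}

#' Center crop or zero-pad to a target size
#'
#' Crops centrally when the input is larger than the target and pads with
#' background (image value 0, label 0) when smaller, per dimension
#' independently.
#'
#' @param sample An [AnnotatedBScan-class].
#' @param target Integer `c(height, width)`.
#' @return An [AnnotatedBScan-class] of exactly the target size.
#' @export
cropOrPad <- function(sample, target) {
  stopifnot(is(sample, "AnnotatedBScan"), length(target) == 2L, all(target >= 1))
  fit <- function(m, th, tw, fill) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(fill, th, tw)
    hs <- min(H, th); ws <- min(W, tw)
    srcR <- floor((H - hs) / 2) + seq_len(hs)
    srcC <- floor((W - ws) / 2) + seq_len(ws)
    dstR <- floor((th - hs) / 2) + seq_len(hs)
    dstC <- floor((tw - ws) / 2) + seq_len(ws)
    out[dstR, dstC] <- m[srcR, srcC]
    out
  }
  AnnotatedBScan(image = fit(sample@image, target[1L], target[2L], 0),
                 mask = fit(sample@mask, target[1L], target[2L], 0L))
}

#' Build k-fold cross-validation splits
#'
#' Shuffles the identifiers deterministically and partitions them into `k`
#' validation folds whose sizes differ by at most one; each fold's training
#' list is the complement.
#'
#' @param sampleIds Character vector of identifiers.
#' @param k Number of folds (>= 2, <= number of ids).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` [SplitSpec-class] objects (with `foldIndex` set).
#' @export
makeFolds <- function(sampleIds, k, seed = 1L) {
  n <- length(sampleIds)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop(sprintf("cannot form %d folds from %d samples", k, n))
  set.seed(seed)
  shuffled <- sample(sampleIds)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    val <- shuffled[starts[i]:stops[i]]
    SplitSpec(train = setdiff(shuffled, val), val = val, foldIndex = i)
  })
}

## ---- file I/O --------------------------------------------------------------

#' Write / read an annotated scan as a PNG pair
#'
#' Images are written as 8-bit grayscale PNG, masks as RGB palette PNG.
#'
#' @param scan An [AnnotatedBScan-class].
#' @param imagePath,maskPath Output (or input) file paths.
#' @param palette A [ClassPalette-class].
#' @return `writeScanPair` invisibly returns the paths; `readScanPair`
#'   returns the restored [AnnotatedBScan-class].
#' @export
writeScanPair <- function(scan, imagePath, maskPath, palette = defaultPalette()) {
  png::writePNG(scan@image, imagePath)
  png::writePNG(encodeMask(scan@mask, palette), maskPath)
  invisible(c(imagePath, maskPath))
}

#' @rdname writeScanPair
#' @export
readScanPair <- function(imagePath, maskPath, palette = defaultPalette()) {
  img <- png::readPNG(imagePath)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- decodeMask(png::readPNG(maskPath), palette)
  AnnotatedBScan(image = img, mask = mask)
}

#' Write / read a split manifest
#'
#' A plain-text manifest with one line per sample:
#' `split <TAB> image-path <TAB> mask-path`.
#'
#' @param entries Data frame with columns `split`, `image`, `mask`.
#' @param path Manifest file path.
#' @return `readManifest` returns the data frame back.
#' @export
writeManifest <- function(entries, path) {
  stopifnot(all(c("split", "image", "mask") %in% names(entries)))
  writeLines(paste(entries$split, entries$image, entries$mask, sep = "\t"), path)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("split", "image", "mask"),
                          stringsAsFactors = FALSE)
  df
}
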