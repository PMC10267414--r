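# The segmentation network: ConvNeXt-style encoder whose stem keeps full
# resolution (stages at 1, 1/2, 1/4, 1/8 scale), and a decoder of 2x
# upsampling, skip concatenation and channel-halving attention blocks,
# finished by a 1x1 output convolution to the class logits.

#' Network architecture configuration
#'
#' Collects every architectural degree of freedom of the segmentation
#' network and validates the decoder channel arithmetic at build time.
#'
#' The defaults (`stageWidths = c(24, 48, 96, 192)`, `stageDepths =
#' c(3, 3, 9, 3)`) follow the ConvNeXt stage layout scaled down so the whole
#' model has about 1.9 million trainable parameters; [countParameters()]
#' reports the exact count for any configuration.
#'
#' @param inChannels Input channels (1 for grayscale B-scans).
#' @param nClasses Number of output classes C (background included).
#' @param stageWidths Channel counts (C1, C2, C3, C4) of the four encoder
#'   stages; C4 is the deepest, 1/8-resolution map.
#' @param stageDepths Number of ConvNeXt blocks per stage; all must be >= 1.
#' @param depthwiseKernel Kernel size of the depthwise convolution inside
#'   each encoder block (7, the large-kernel ConvNeXt choice).
#' @param camReduction Channel-attention MLP bottleneck ratio `r`
#'   (clamped to `C/2` for narrow maps).
#' @param samKernel Spatial-attention convolution size (odd; 7 in the
#'   published module).
#' @param decoderKernel Kernel of the depthwise-separable convolutions in
#'   the DE-CBAM decoder blocks.
#' @param attentionVariant `"DE-CBAM"` (default) or `"CBAM"`; the latter
#'   keeps CBAM unchanged and halves channels with a plain 1x1 projection,
#'   giving the ablation baseline.
#' @param upsampleMode `"bilinear"` (parameter-free, default) or
#'   `"transposed"` (learned 2x2 stride-2 transposed convolution).
#' @param layerScale Initial value of the per-channel residual scaling in
#'   the encoder blocks.
#' @param initSd Standard deviation of the weight initialization; `NULL`
#'   (default) scales each layer by its fan-in (He initialization).
#' @return A validated configuration list of class `"networkConfig"`.
#' @export
networkConfig <- function(inChannels = 1L, nClasses = 9L,
                          stageWidths = c(24L, 48L, 96L, 192L),
                          stageDepths = c(3L, 3L, 9L, 3L),
                          depthwiseKernel = 7L, camReduction = 16L,
                          samKernel = 7L, decoderKernel = 3L,
                          attentionVariant = c("DE-CBAM", "CBAM"),
                          upsampleMode = c("bilinear", "transposed"),
                          layerScale = 1e-6, initSd = NULL) {
  attentionVariant <- match.arg(attentionVariant)
  upsampleMode <- match.arg(upsampleMode)
  stageWidths <- as.integer(stageWidths)
  stageDepths <- as.integer(stageDepths)
  if (length(stageWidths) != 4L || any(stageWidths < 1L))
    stop("stageWidths must be four positive channel counts")
  if (length(stageDepths) != 4L || any(stageDepths < 1L))
    stop("stageDepths must be four positive block counts")
  if (nClasses < 2L) stop("nClasses must be at least 2")
  if (samKernel %% 2L != 1L) stop("samKernel must be odd")
  # decoder channel bookkeeping: each stage concatenates the upsampled deep
  # map with the next-shallower skip and halves the total
  dec <- decoderChannels(stageWidths)
  cfg <- list(inChannels = as.integer(inChannels), nClasses = as.integer(nClasses),
              stageWidths = stageWidths, stageDepths = stageDepths,
              depthwiseKernel = as.integer(depthwiseKernel),
              camReduction = as.integer(camReduction),
              samKernel = as.integer(samKernel),
              decoderKernel = as.integer(decoderKernel),
              attentionVariant = attentionVariant,
              upsampleMode = upsampleMode,
              layerScale = layerScale, initSd = initSd,
              decoderIn = dec$inCh, decoderOut = dec$outCh)
  class(cfg) <- "networkConfig"
  cfg
}

# Channel arithmetic of the three decoder stages; errors at configuration
# time (not run time) when a concatenation cannot be halved.
decoderChannels <- function(widths) {
  deep <- widths[4L]
  inCh <- integer(3); outCh <- integer(3)
  for (j in 1:3) {
    cin <- widths[4L - j] + deep
    if (cin %% 2L != 0L)
      stop(sprintf(paste0("decoder stage %d would concatenate %d + %d = %d ",
                          "channels, which cannot be halved; adjust stageWidths"),
                   j, widths[4L - j], deep, cin))
    inCh[j] <- cin
    deep <- cin %/% 2L
    outCh[j] <- deep
  }
  list(inCh = inCh, outCh = outCh)
}

#' Build a segmentation model
#'
#' Initializes all weights of the configured network deterministically from
#' a seed.
#'
#' @param config A [networkConfig()].
#' @param seed Integer RNG seed for the weight initialization.
#' @return A [SegmentationModel-class].
#' @export
buildNetwork <- function(config = networkConfig(), seed = 1L) {
  stopifnot(inherits(config, "networkConfig"))
  set.seed(seed)
  sd <- config$initSd
  w <- config$stageWidths
  stem <- list(conv = convInit(config$inChannels, w[1L], 4L, sd = sd),
               ln = lnInit(w[1L]))
  stages <- vector("list", 4L)
  for (i in 1:4) {
    st <- list()
    if (i > 1L)
      st$down <- list(ln = lnInit(w[i - 1L]),
                      conv = convInit(w[i - 1L], w[i], 2L, sd = sd))
    st$blocks <- lapply(seq_len(config$stageDepths[i]), function(b)
      cnxBlockInit(w[i], config$depthwiseKernel, sd = sd,
                   layerScale = config$layerScale))
    stages[[i]] <- st
  }
  attInit <- if (config$attentionVariant == "DE-CBAM") {
    function(C) deCbamInit(C, config$camReduction, config$samKernel,
                           config$decoderKernel, sd = sd)
  } else {
    function(C) cbamProjInit(C, config$camReduction, config$samKernel, sd = sd)
  }
  decoder <- vector("list", 3L)
  upIn <- c(w[4L], config$decoderOut[1:2])
  for (j in 1:3) {
    dj <- list(att = attInit(config$decoderIn[j]))
    if (config$upsampleMode == "transposed")
      dj$up <- tconvInit(upIn[j], upIn[j], sd = sd)
    decoder[[j]] <- dj
  }
  sdOut <- if (is.null(sd)) heSd(config$decoderOut[3L]) else sd
  out <- list(W = matrix(stats::rnorm(config$decoderOut[3L] * config$nClasses, 0, sdOut),
                         config$decoderOut[3L], config$nClasses),
              b = numeric(config$nClasses))
  new("SegmentationModel", config = unclass(config),
      params = list(stem = stem, stages = stages, decoder = decoder, out = out))
}

checkDivisible <- function(H, W) {
  if (H %% 8L != 0L || W %% 8L != 0L)
    stop(sprintf(paste0("input size %d x %d is not divisible by 8; ",
                        "crop or pad first (see cropOrPad())"), H, W))
}

## ---- internal forward / backward -----------------------------------------

netForward <- function(params, cfg, img, keepCache = TRUE) {
  H <- nrow(img); W <- ncol(img)
  checkDivisible(H, W)
  x <- matrix(as.numeric(img), H * W, cfg$inChannels)
  cache <- list(H = H, W = W)

  gStem <- convGeometry(H, W, 4L, padTop = 1L, padLeft = 1L,
                        padBottom = 2L, padRight = 2L)
  cv <- convForward(params$stem$conv, x, gStem, cfg$inChannels, keepCache)
  ln <- lnForward(params$stem$ln, cv$y, keepCache = keepCache)
  cache$stem <- list(conv = cv$cache, ln = ln$cache)
  f <- ln$y
  h <- H; w <- W

  feats <- vector("list", 4L)
  dims <- vector("list", 4L)
  cache$stages <- vector("list", 4L)
  for (i in 1:4) {
    sc <- list()
    if (i > 1L) {
      dln <- lnForward(params$stages[[i]]$down$ln, f, keepCache = keepCache)
      gD <- convGeometry(h, w, 2L, stride = 2L, padTop = 0L, padLeft = 0L,
                         padBottom = 0L, padRight = 0L)
      dcv <- convForward(params$stages[[i]]$down$conv, dln$y, gD,
                         cfg$stageWidths[i - 1L], keepCache)
      sc$down <- list(ln = dln$cache, conv = dcv$cache)
      f <- dcv$y
      h <- h %/% 2L; w <- w %/% 2L
    }
    sc$blocks <- vector("list", length(params$stages[[i]]$blocks))
    for (b in seq_along(params$stages[[i]]$blocks)) {
      bk <- cnxBlockForward(params$stages[[i]]$blocks[[b]], f, h, w, keepCache)
      sc$blocks[[b]] <- bk$cache
      f <- bk$y
    }
    feats[[i]] <- f
    dims[[i]] <- c(h, w)
    cache$stages[[i]] <- sc
  }
  cache$dims <- dims
  cache$feats <- feats

  d <- feats[[4L]]
  h <- dims[[4L]][1L]; w <- dims[[4L]][2L]
  cache$decoder <- vector("list", 3L)
  decOut <- vector("list", 3L)
  decDims <- vector("list", 3L)
  for (j in 1:3) {
    dc <- list()
    if (cfg$upsampleMode == "transposed") {
      tc <- tconvForward(params$decoder[[j]]$up, d, h, w, keepCache)
      u <- tc$y
      dc$up <- tc$cache
    } else {
      u <- upForward(d, h, w)
    }
    h <- 2L * h; w <- 2L * w
    skip <- feats[[4L - j]]
    dc$upCh <- ncol(u)
    catF <- cbind(u, skip)
    att <- if (cfg$attentionVariant == "DE-CBAM")
      deCbamForward(params$decoder[[j]]$att, catF, h, w, keepCache)
    else
      cbamProjForward(params$decoder[[j]]$att, catF, h, w, keepCache)
    dc$att <- att$cache
    d <- att$y
    decOut[[j]] <- d
    decDims[[j]] <- c(h, w)
    cache$decoder[[j]] <- dc
  }
  cache$decOut <- decOut
  cache$decDims <- decDims

  logits <- d %*% params$out$W
  logits <- logits + rep(params$out$b, each = nrow(logits))
  cache$dLast <- d
  list(logits = logits, cache = cache)
}

# Backward pass; dlogits is (H*W) x C.  `taps` names decoder activations
# whose incoming gradients should be captured: "de_cbam1".."de_cbam3"
# (decoder stages, deepest first) and "output_conv" (the logits).
netBackward <- function(params, cfg, cache, dlogits, taps = character()) {
  tapGrads <- list()
  if ("output_conv" %in% taps) tapGrads$output_conv <- dlogits

  gradOut <- list(W = crossprod(cache$dLast, dlogits), b = colSums(dlogits))
  dd <- dlogits %*% t(params$out$W)

  decGrads <- vector("list", 3L)
  dfeats <- vector("list", 4L)
  for (j in 3:1) {
    tapName <- paste0("de_cbam", j)
    if (tapName %in% taps) tapGrads[[tapName]] <- dd
    dc <- cache$decoder[[j]]
    ab <- if (cfg$attentionVariant == "DE-CBAM")
      deCbamBackward(params$decoder[[j]]$att, dc$att, dd)
    else
      cbamProjBackward(params$decoder[[j]]$att, dc$att, dd)
    gj <- list(att = ab$grads)
    upCh <- dc$upCh
    du <- ab$dx[, seq_len(upCh), drop = FALSE]
    dskip <- ab$dx[, (upCh + 1L):ncol(ab$dx), drop = FALSE]
    dfeats[[4L - j]] <- dskip
    hIn <- cache$decDims[[j]][1L] %/% 2L
    wIn <- cache$decDims[[j]][2L] %/% 2L
    if (cfg$upsampleMode == "transposed") {
      tb <- tconvBackward(params$decoder[[j]]$up, dc$up, du)
      gj$up <- tb$grads
      dd <- tb$dx
    } else {
      dd <- upBackward(du, hIn, wIn)
    }
    decGrads[[j]] <- gj
  }
  dfeats[[4L]] <- dd

  stageGrads <- vector("list", 4L)
  df <- NULL
  for (i in 4:1) {
    df <- if (is.null(df)) dfeats[[i]] else df + dfeats[[i]]
    sg <- list()
    blocks <- params$stages[[i]]$blocks
    sg$blocks <- vector("list", length(blocks))
    for (b in rev(seq_along(blocks))) {
      bb <- cnxBlockBackward(blocks[[b]], cache$stages[[i]]$blocks[[b]], df)
      sg$blocks[[b]] <- bb$grads
      df <- bb$dx
    }
    if (i > 1L) {
      cb <- convBackward(params$stages[[i]]$down$conv,
                         cache$stages[[i]]$down$conv, df)
      lb <- lnBackward(params$stages[[i]]$down$ln,
                       cache$stages[[i]]$down$ln, cb$dx)
      sg$down <- list(ln = lb$grads, conv = cb$grads)
      df <- lb$dx
    }
    stageGrads[[i]] <- sg
  }

  lb <- lnBackward(params$stem$ln, cache$stem$ln, df)
  cb <- convBackward(params$stem$conv, cache$stem$conv, lb$dx)
  list(grads = list(stem = list(conv = cb$grads, ln = lb$grads),
                    stages = stageGrads, decoder = decGrads, out = gradOut),
       tapGrads = tapGrads)
}

## ---- exported interface ---------------------------------------------------

#' Encode an image into the four-scale feature pyramid
#'
#' Runs the ConvNeXt-style encoder: the stem applies no spatial reduction
#' (full-resolution F1'), and stages 2-4 each downsample by 2, giving maps
#' at 1, 1/2, 1/4 and 1/8 of the input resolution.
#'
#' @param model A [SegmentationModel-class].
#' @param image Numeric `H x W` matrix with `H`, `W` divisible by 8.
#' @return A [FeaturePyramid-class].
#' @export
encodeFeatures <- function(model, image) {
  fw <- netForward(model@params, model@config, image, keepCache = FALSE)
  dims <- fw$cache$dims
  maps <- lapply(1:4, function(i)
    asFeatureArray(fw$cache$feats[[i]], dims[[i]][1L], dims[[i]][2L]))
  new("FeaturePyramid", maps = maps)
}

#' Full network forward pass
#'
#' @param model A [SegmentationModel-class].
#' @param image Numeric `H x W` matrix (values in \[0,1\]), dims divisible
#'   by 8.
#' @return A list with `logits` (`H x W x C` array of unbounded scores) and
#'   `probs` (softmax over classes at every pixel).
#' @export
networkForward <- function(model, image) {
  fw <- netForward(model@params, model@config, image, keepCache = FALSE)
  H <- nrow(image); W <- ncol(image)
  list(logits = asFeatureArray(fw$logits, H, W),
       probs = asFeatureArray(softmaxRows(fw$logits), H, W))
}

#' Predict a label mask
#'
#' Argmax over the per-pixel class scores.
#'
#' @inheritParams networkForward
#' @return Integer `H x W` matrix of labels in `0..C-1`.
#' @export
predictMask <- function(model, image) {
  fw <- netForward(model@params, model@config, image, keepCache = FALSE)
  matrix(max.col(fw$logits, ties.method = "first") - 1L,
         nrow(image), ncol(image))
}

#' Count trainable parameters
#'
#' Total number of trainable weights of a model or of the model a
#' configuration would build.
#'
#' @param x A [SegmentationModel-class] or a [networkConfig()].
#' @return Integer parameter count.
#' @export
countParameters <- function(x) {
  if (inherits(x, "networkConfig")) x <- buildNetwork(x, seed = 1L)
  stopifnot(is(x, "SegmentationModel"))
  paramCount(x@params)
}

#' Save / load a model as plain JSON
#'
#' Checkpoints embed the architecture configuration alongside every weight
#' array, so a file fully reconstructs the model.
#'
#' @param model A [SegmentationModel-class].
#' @param path File path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   restored [SegmentationModel-class].
#' @export
saveModel <- function(model, path) {
  payload <- list(config = model@config, params = model@params)
  # serializeJSON preserves types, dimensions and the nested parameter
  # structure exactly, while remaining plain text
  writeLines(jsonlite::serializeJSON(payload, digits = NA), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  payload <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  new("SegmentationModel", config = payload$config, params = payload$params)
}
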