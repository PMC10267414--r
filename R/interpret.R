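# Model interpretation: per-pixel predictive-entropy uncertainty maps and
# gradient-weighted class activation heatmaps at chosen decoder layers.

#' Per-pixel entropy uncertainty map
#'
#' @slot values Numeric `H x W` matrix of entropies, each in \[0, log m\].
#' @slot m Number of categories.
#' @slot logBase Logarithm base used (e for nats, 2 for bits).
#' @export
setClass("UncertaintyMap",
         representation(values = "matrix", m = "integer", logBase = "numeric"))

setValidity("UncertaintyMap", function(object) {
  hmax <- log(object@m, base = object@logBase)
  if (length(object@values) &&
      (min(object@values) < -1e-9 || max(object@values) > hmax + 1e-9))
    return("entropies must lie in [0, log m]")
  TRUE
})

setMethod("show", "UncertaintyMap", function(object) {
  cat(sprintf("UncertaintyMap %d x %d, m = %d, range [%.4f, %.4f] (max %.4f)\n",
              nrow(object@values), ncol(object@values), object@m,
              min(object@values), max(object@values),
              log(object@m, base = object@logBase)))
})

#' @describeIn UncertaintyMap Entropy-matrix accessor.
#' @param x An `UncertaintyMap`.
#' @export
uncertaintyValues <- function(x) x@values

#' Class activation heatmap
#'
#' @slot values Non-negative `H x W` matrix scaled to \[0, 1\] (identically
#'   zero when the class score has no gradient), upsampled to image size.
#' @slot native The same map at the tapped layer's own resolution (useful
#'   for comparing spatial frequency content across depths, which the
#'   bilinear upsampling would otherwise smooth away).
#' @slot layer Source layer identifier.
#' @slot classId Target class index (0-based).
#' @export
setClass("Heatmap",
         representation(values = "matrix", native = "matrix",
                        layer = "character", classId = "integer"))

setValidity("Heatmap", function(object) {
  v <- object@values
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("heatmap values must lie in [0, 1]")
  TRUE
})

setMethod("show", "Heatmap", function(object) {
  cat(sprintf("Heatmap %d x %d for class %d at %s\n",
              nrow(object@values), ncol(object@values),
              object@classId, object@layer))
})

#' @describeIn Heatmap Relevance-matrix accessor (image resolution).
#' @param x A `Heatmap`.
#' @export
heatmapValues <- function(x) x@values

#' @describeIn Heatmap Relevance matrix at the tapped layer's resolution.
#' @export
heatmapNative <- function(x) x@native

#' Normalize raw per-pixel class scores to probabilities
#'
#' Per pixel, the m raw values are translated so the minimum is strictly
#' positive (shift `-min + eps` applied only when the minimum is not
#' already positive, with `eps` equal to 1e-6 of the per-pixel value
#' range), then divided by their sum.  The result is a valid probability
#' distribution at every pixel, usable by [entropyMap()] whether the raw
#' values are softmax outputs or unnormalized scores.
#'
#' @param scores `H x W x m` array (or `n x m` matrix) of raw class values.
#' @return Array (or matrix) of the same shape with rows summing to 1.
#' @export
normalizeScores <- function(scores) {
  isArr <- !is.matrix(scores)
  z <- if (isArr) asFeatureMatrix(scores) else scores
  m <- ncol(z)
  if (m < 2L) stop("need at least 2 class values per pixel")
  mins <- as.numeric(do.call(pmin, asplit(z, 2L)))
  maxs <- as.numeric(do.call(pmax, asplit(z, 2L)))
  eps <- 1e-6 * pmax(maxs - mins, 1)
  shift <- ifelse(mins <= 0, -mins + eps, 0)
  z <- z + shift
  p <- z / rowSums(z)
  if (isArr) array(p, dim(scores)) else p
}

#' Predictive-entropy uncertainty map
#'
#' Per-pixel Shannon entropy `H = -sum(p * log p)` of the normalized class
#' probabilities (`0 * log 0 := 0`); high entropy marks pixels where the
#' model's output distribution is close to uniform, i.e. uncertain.
#'
#' @param probs `H x W x m` array of per-pixel probability distributions
#'   (see [normalizeScores()]); an `n x m` matrix is also accepted.
#' @param logBase Logarithm base (default natural log).
#' @return An [UncertaintyMap-class] (for matrix input, the values matrix
#'   has one row per pixel row of the input).
#' @export
entropyMap <- function(probs, logBase = exp(1)) {
  isArr <- !is.matrix(probs)
  p <- if (isArr) asFeatureMatrix(probs) else probs
  m <- ncol(p)
  pl <- p * log(p, base = logBase)
  pl[p == 0] <- 0
  h <- pmax(-rowSums(pl), 0)
  values <- if (isArr) matrix(h, dim(probs)[1L], dim(probs)[2L])
            else matrix(h, nrow(p), 1L)
  new("UncertaintyMap", values = values, m = as.integer(m),
      logBase = logBase)
}

#' Gradient-weighted class activation heatmap
#'
#' Adapts gradient-based class activation mapping to dense segmentation:
#' the class score is the sum of the class's logits over the pixels
#' predicted as that class; channel weights are the spatial averages of the
#' gradients of that score with respect to the chosen layer's activations;
#' the heatmap is the rectified channel-weighted activation sum, upsampled
#' to image size and min-max scaled to \[0, 1\].
#'
#' @param model A [SegmentationModel-class].
#' @param image Numeric `H x W` matrix, dims divisible by 8.
#' @param layer One of `"de_cbam1"`, `"de_cbam2"`, `"de_cbam3"` (decoder
#'   attention stages, deepest first at 1/4, 1/2 and full resolution) or
#'   `"output_conv"` (the logits).
#' @param classId Target class index in `0..C-1`.
#' @return A [Heatmap-class] at image resolution.  If the class is absent
#'   from the prediction the map is identically zero (with a warning).
#' @export
activationHeatmap <- function(model, image,
                              layer = c("de_cbam1", "de_cbam2", "de_cbam3",
                                        "output_conv"),
                              classId) {
  layer <- match.arg(layer)
  cfg <- model@config
  classId <- as.integer(classId)
  if (classId < 0L || classId >= cfg$nClasses)
    stop(sprintf("classId must lie in 0..%d", cfg$nClasses - 1L))
  H <- nrow(image); W <- ncol(image)
  fw <- netForward(model@params, cfg, image, keepCache = TRUE)
  pred <- max.col(fw$logits, ties.method = "first") - 1L
  sel <- pred == classId
  zero <- function() new("Heatmap", values = matrix(0, H, W),
                         native = matrix(0, H, W),
                         layer = layer, classId = classId)
  if (!any(sel)) {
    warning(sprintf("class %d absent from the prediction; returning a zero map",
                    classId))
    return(zero())
  }
  dlogits <- matrix(0, nrow(fw$logits), cfg$nClasses)
  dlogits[sel, classId + 1L] <- 1
  if (layer == "output_conv") {
    act <- fw$logits
    grad <- dlogits
    th <- H; tw <- W
  } else {
    j <- as.integer(substring(layer, 8L))
    bw <- netBackward(model@params, cfg, fw$cache, dlogits, taps = layer)
    act <- fw$cache$decOut[[j]]
    grad <- bw$tapGrads[[layer]]
    th <- fw$cache$decDims[[j]][1L]; tw <- fw$cache$decDims[[j]][2L]
  }
  wgt <- colMeans(grad)
  heat <- pmax(drop(act %*% wgt), 0)
  hm <- matrix(heat, th, tw)
  native <- if (max(hm) > 0) hm / max(hm) else hm
  while (nrow(hm) < H) {
    hm <- matrix(upForward(matrix(as.numeric(hm), ncol = 1L),
                           nrow(hm), ncol(hm)),
                 2L * nrow(hm), 2L * ncol(hm))
  }
  mx <- max(hm)
  if (mx > 0) hm <- hm / mx
  new("Heatmap", values = hm, native = native, layer = layer,
      classId = classId)
}
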