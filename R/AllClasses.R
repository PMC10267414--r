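#' @import methods
NULL

#' An annotated B-scan: image plus pixel-exact label mask
#'
#' Couples one grayscale OCT B-scan (values in \[0,1\]) with an integer
#' class-label grid of identical height and width.  Label 0 is the
#' background; labels 1..C-1 are the retinal layer classes.
#'
#' @slot image Numeric `H x W` matrix with values in \[0, 1\].
#' @slot mask Integer-valued `H x W` matrix of class labels, 0-based.
#' @export
setClass("AnnotatedBScan",
         representation(image = "matrix", mask = "matrix"))

setValidity("AnnotatedBScan", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask must have identical dimensions")
  if (length(object@image) &&
      (min(object@image) < 0 || max(object@image) > 1))
    msg <- c(msg, "image values must lie in [0, 1]")
  if (length(object@mask) &&
      (any(object@mask != round(object@mask)) || min(object@mask) < 0))
    msg <- c(msg, "mask values must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedBScan
#'
#' @param image Numeric `H x W` matrix in \[0, 1\].
#' @param mask Integer `H x W` label matrix (0 = background).
#' @return An [AnnotatedBScan-class] object.
#' @export
AnnotatedBScan <- function(image, mask) {
  new("AnnotatedBScan", image = image, mask = matrix(as.integer(round(mask)),
                                                     nrow(mask), ncol(mask)))
}

#' @describeIn AnnotatedBScan Image matrix accessor.
#' @param x An `AnnotatedBScan`.
#' @export
scanImage <- function(x) x@image

#' @describeIn AnnotatedBScan Label-mask accessor.
#' @export
scanMask <- function(x) x@mask

setMethod("show", "AnnotatedBScan", function(object) {
  d <- dim(object@image)
  cat(sprintf("AnnotatedBScan %d x %d, %d label(s) present, %.2f%% foreground\n",
              d[1], d[2], length(unique(as.integer(object@mask))),
              100 * mean(object@mask != 0L)))
})

#' Ordered, non-crossing layer boundary curves
#'
#' Holds `nLayers + 1` real-valued boundary curves, one row position per
#' image column, ordered top to bottom (the row index increases downward).
#' The band of layer `j` spans the half-open interval
#' `[boundary_j(x), boundary_{j+1}(x))` in every column `x`.
#'
#' @slot boundaries Numeric `(nLayers + 1) x W` matrix of row positions.
#' @slot height Frame height in pixels; all curves lie in \[0, height\].
#' @export
setClass("LayerBoundarySet",
         representation(boundaries = "matrix", height = "numeric"))

setValidity("LayerBoundarySet", function(object) {
  b <- object@boundaries
  msg <- character()
  if (nrow(b) < 2L) msg <- c(msg, "need at least two boundary curves")
  if (any(diff(b) < 0)) msg <- c(msg, "boundaries must be non-crossing (ordered per column)")
  if (length(b) && (min(b) < 0 || max(b) > object@height))
    msg <- c(msg, "boundaries must lie within [0, height]")
  if (length(msg)) msg else TRUE
})

#' @describeIn LayerBoundarySet Boundary-matrix accessor
#'   (`(nLayers + 1) x W`).
#' @param x A `LayerBoundarySet`.
#' @export
boundaryMatrix <- function(x) x@boundaries

setMethod("show", "LayerBoundarySet", function(object) {
  cat(sprintf("LayerBoundarySet: %d bands, width %d, frame height %g\n",
              nrow(object@boundaries) - 1L, ncol(object@boundaries),
              object@height))
})

#' Class palette mapping label indices to RGB colors
#'
#' Ordered, injective mapping from class index (0-based, class 0 = black
#' background) to an RGB triple used in annotation masks.
#'
#' @slot colors Integer `n x 3` matrix of RGB values in \[0, 255\].
#' @slot labels Character vector of class names, same length as rows.
#' @export
setClass("ClassPalette",
         representation(colors = "matrix", labels = "character"))

setValidity("ClassPalette", function(object) {
  msg <- character()
  if (ncol(object@colors) != 3L) msg <- c(msg, "colors must have 3 columns")
  if (nrow(object@colors) != length(object@labels))
    msg <- c(msg, "one label per color required")
  key <- object@colors %*% c(65536, 256, 1)
  if (anyDuplicated(key)) msg <- c(msg, "palette colors must be distinct")
  if (length(object@colors) &&
      (min(object@colors) < 0 || max(object@colors) > 255))
    msg <- c(msg, "RGB values must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClassPalette Number of classes (including background).
#' @param x A `ClassPalette`.
#' @export
nClasses <- function(x) nrow(x@colors)

#' @describeIn ClassPalette RGB color matrix accessor.
#' @export
paletteColors <- function(x) x@colors

#' @describeIn ClassPalette Class-label accessor.
#' @export
paletteLabels <- function(x) x@labels

setMethod("show", "ClassPalette", function(object) {
  cat("ClassPalette with", nrow(object@colors), "classes:\n")
  for (i in seq_along(object@labels))
    cat(sprintf("  %d %-9s (%3d,%3d,%3d)\n", i - 1L, object@labels[i],
                object@colors[i, 1], object@colors[i, 2], object@colors[i, 3]))
})

#' Four-scale encoder feature pyramid
#'
#' The encoder's output maps F1'..F4' at full, 1/2, 1/4 and 1/8 of the input
#' resolution.  Each element is an `H x W x C` array (channels last).
#'
#' @slot maps List of four feature arrays, shallowest (full resolution)
#'   first.
#' @export
setClass("FeaturePyramid", representation(maps = "list"))

setValidity("FeaturePyramid", function(object) {
  if (length(object@maps) != 4L) return("a feature pyramid has four levels")
  d1 <- dim(object@maps[[1]])
  for (i in 2:4) {
    di <- dim(object@maps[[i]])
    if (!all(di[1:2] * 2^(i - 1) == d1[1:2]))
      return(sprintf("level %d must be at 1/%d of the input resolution", i, 2^(i - 1)))
  }
  TRUE
})

#' @describeIn FeaturePyramid List of the four feature arrays.
#' @param x A `FeaturePyramid`.
#' @export
pyramidMaps <- function(x) x@maps

setMethod("show", "FeaturePyramid", function(object) {
  cat("FeaturePyramid:\n")
  for (i in 1:4) {
    d <- dim(object@maps[[i]])
    cat(sprintf("  F%d': %d x %d x %d\n", i, d[1], d[2], d[3]))
  }
})

#' Train/validation/test split specification
#'
#' @slot train,val,test Character vectors of sample identifiers; pairwise
#'   disjoint, jointly covering the declared samples.
#' @slot foldIndex Integer fold number (`NA` outside cross-validation).
#' @export
setClass("SplitSpec",
         representation(train = "character", val = "character",
                        test = "character", foldIndex = "integer"))

setValidity("SplitSpec", function(object) {
  all3 <- c(object@train, object@val, object@test)
  if (anyDuplicated(all3)) return("split lists must be pairwise disjoint")
  TRUE
})

#' Construct a SplitSpec
#' @param train,val,test Character identifier vectors.
#' @param foldIndex Optional fold number.
#' @return A [SplitSpec-class] object.
#' @export
SplitSpec <- function(train, val, test = character(), foldIndex = NA_integer_) {
  new("SplitSpec", train = as.character(train), val = as.character(val),
      test = as.character(test), foldIndex = as.integer(foldIndex))
}

#' @describeIn SplitSpec Accessors for the three identifier lists.
#' @param x A `SplitSpec`.
#' @export
trainIds <- function(x) x@train

#' @describeIn SplitSpec Validation identifiers.
#' @export
valIds <- function(x) x@val

#' @describeIn SplitSpec Test identifiers.
#' @export
testIds <- function(x) x@test

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: %d train / %d val / %d test%s\n",
              length(object@train), length(object@val), length(object@test),
              if (!is.na(object@foldIndex))
                sprintf(" (fold %d)", object@foldIndex) else ""))
})

#' Segmentation model: architecture configuration plus weights
#'
#' @slot config Network configuration list from [networkConfig()].
#' @slot params Nested list of weight arrays.
#' @export
setClass("SegmentationModel",
         representation(config = "list", params = "list"))

#' @describeIn SegmentationModel Configuration accessor.
#' @param x A `SegmentationModel`.
#' @export
modelConfig <- function(x) x@config

#' @describeIn SegmentationModel Weight accessor.
#' @export
modelParams <- function(x) x@params

setMethod("show", "SegmentationModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("SegmentationModel (%s decoder attention)\n",
                     "  stage widths: %s | depths: %s\n",
                     "  classes: %d | parameters: %s\n"),
              cfg$attentionVariant,
              paste(cfg$stageWidths, collapse = "/"),
              paste(cfg$stageDepths, collapse = "/"),
              cfg$nClasses,
              format(paramCount(object@params), big.mark = ",")))
})
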