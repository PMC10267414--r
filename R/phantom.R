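# Synthetic OCT B-scan phantoms: ordered non-crossing layer bands with
# smooth undulation, a central foveal pit, per-layer reflectance and
# multiplicative speckle, plus pixel-exact label masks.  Every downstream
# stage of the package is testable on these without any clinical data.

#' Phantom generator configuration
#'
#' Defaults emulate a fovea-centred healthy B-scan at the native 500 x 750
#' frame: eight retinal layer bands (NFL..RPE) over a black background, with
#' per-layer mean thicknesses whose ordering follows the annotated data
#' (GCL+IPL, ONL and ELM+IS thick; OS and NFL thin) and whose sum is
#' calibrated so the rendered foreground fraction matches the reported
#' average annotated fraction of about 14.8%.
#'
#' @param height,width Frame size in pixels.
#' @param nLayers Number of layer classes (default 8; total classes are
#'   `nLayers + 1` including background).
#' @param meanThickness Mean band thickness in pixels, one value per layer
#'   (recycled if scalar).
#' @param boundaryAmplitude Peak undulation of each band thickness, pixels.
#' @param boundaryWavelength Dominant undulation wavelength, pixels.
#' @param pitDepth Depth of the central foveal pit, pixels (0 disables).
#' @param pitWidth Gaussian sigma of the pit, pixels.
#' @param layerIntensities Reflectance in \[0,1\] per layer (bright NFL and
#'   RPE, dark ONL, as in OCT).
#' @param backgroundIntensity Background reflectance in \[0,1\].
#' @param speckleLevel Multiplicative speckle scale (>= 0); the image is
#'   `I * (1 + speckleLevel * N(0,1))`, clipped to \[0,1\].
#' @param topMargin Rows above the first boundary; `NA` centres the stack
#'   at 40% of the free height.
#' @param seed Default RNG seed used when an operation is not given one.
#' @return A validated list of class `"phantomConfig"`.
#' @export
phantomConfig <- function(height = 500L, width = 750L, nLayers = 8L,
                          meanThickness = c(6, 15, 9, 8, 14, 13, 5, 9),
                          boundaryAmplitude = 2, boundaryWavelength = 250,
                          pitDepth = 25, pitWidth = 60,
                          layerIntensities = c(0.70, 0.40, 0.20, 0.55,
                                               0.12, 0.60, 0.30, 0.85),
                          backgroundIntensity = 0.03,
                          speckleLevel = 0.10, topMargin = NA,
                          seed = 1L) {
  nLayers <- as.integer(nLayers)
  if (nLayers < 1L) stop("nLayers must be >= 1")
  meanThickness <- rep_len(as.numeric(meanThickness), nLayers)
  layerIntensities <- rep_len(as.numeric(layerIntensities), nLayers)
  if (any(c(meanThickness, boundaryAmplitude, pitDepth, pitWidth) < 0))
    stop("thickness, amplitude and pit parameters must be >= 0")
  if (speckleLevel < 0) stop("speckleLevel must be >= 0")
  if (any(layerIntensities < 0 | layerIntensities > 1) ||
      backgroundIntensity < 0 || backgroundIntensity > 1)
    stop("intensities must lie in [0, 1]")
  if (is.na(topMargin))
    topMargin <- 0.4 * (height - sum(meanThickness))
  if (topMargin < 0 || topMargin + sum(meanThickness) >= height)
    stop("band stack does not fit in the frame: reduce thicknesses or topMargin")
  cfg <- list(height = as.integer(height), width = as.integer(width),
              nLayers = nLayers, meanThickness = meanThickness,
              boundaryAmplitude = boundaryAmplitude,
              boundaryWavelength = boundaryWavelength,
              pitDepth = pitDepth, pitWidth = pitWidth,
              layerIntensities = layerIntensities,
              backgroundIntensity = backgroundIntensity,
              speckleLevel = speckleLevel, topMargin = topMargin,
              seed = as.integer(seed))
  class(cfg) <- "phantomConfig"
  cfg
}

#' Phantom configuration for a macular-crop frame
#'
#' A phantom emulating a crop centred on the retina rather than the full
#' B-scan frame: the eight bands fill most of the (small) frame, as they do
#' in a zoomed macular window.  Geometry scales with the frame size so the
#' bands always fit.  Used for compact CPU-scale training studies.
#'
#' @param height,width Frame size in pixels.
#' @param speckleLevel Multiplicative speckle scale.
#' @param seed Default RNG seed.
#' @return A [phantomConfig()].
#' @export
cropPhantomConfig <- function(height = 64L, width = 96L, speckleLevel = 0.10,
                              seed = 1L) {
  phantomConfig(height = height, width = width, nLayers = 8L,
                meanThickness = height * 5 / 64,
                boundaryAmplitude = height * 1.5 / 64,
                boundaryWavelength = width * 2 / 3,
                pitDepth = height / 16, pitWidth = width / 8,
                topMargin = height * 6 / 64,
                speckleLevel = speckleLevel, seed = seed)
}

# Smooth zero-mean undulation bounded by 1 in absolute value: three
# random-phase sinusoids with geometrically decreasing amplitude.
smoothUndulation <- function(width, wavelength) {
  x <- seq_len(width)
  amp <- c(1, 0.5, 0.25)
  u <- 0
  for (h in 1:3) {
    phase <- stats::runif(1, 0, 2 * pi)
    u <- u + amp[h] * sin(2 * pi * h * x / wavelength + phase)
  }
  u / sum(amp)
}

#' Sample layer boundary curves
#'
#' Draws `nLayers + 1` smooth, non-crossing boundary curves by cumulative
#' thickness stacking: the top boundary undulates around the top margin,
#' each band thickness undulates around its mean (bounded by
#' `boundaryAmplitude`), and a centred Gaussian-shaped foveal pit displaces
#' the inner (upper) boundaries downward with a weight that decreases with
#' depth, thinning the inner layers at the fovea.  Non-crossing is
#' guaranteed by construction (non-negative thicknesses, bottom-up pit
#' clamping).
#'
#' @param config A [phantomConfig()].
#' @param rngSeed Integer seed making the draw deterministic.
#' @return A [LayerBoundarySet-class].
#' @export
sampleBoundaries <- function(config, rngSeed = config$seed) {
  stopifnot(inherits(config, "phantomConfig"))
  maxSpan <- config$topMargin + sum(config$meanThickness) +
    config$boundaryAmplitude * (config$nLayers + 1)
  if (maxSpan >= config$height)
    stop("band stack cannot fit in the frame at this amplitude")
  set.seed(rngSeed)
  W <- config$width; n <- config$nLayers
  b <- matrix(0, n + 1L, W)
  b[1L, ] <- config$topMargin +
    config$boundaryAmplitude * smoothUndulation(W, config$boundaryWavelength)
  for (j in seq_len(n)) {
    thick <- pmax(0, config$meanThickness[j] +
                    config$boundaryAmplitude *
                      smoothUndulation(W, config$boundaryWavelength))
    b[j + 1L, ] <- b[j, ] + thick
  }
  if (config$pitDepth > 0) {
    x <- seq_len(W)
    bump <- config$pitDepth * exp(-0.5 * ((x - (W + 1) / 2) / config$pitWidth)^2)
    wgt <- (n:0) / n                       # full displacement at the top, none at the bottom
    for (j in (n:1)) {                     # bottom-up clamp keeps the ordering
      b[j, ] <- pmin(b[j, ] + bump * wgt[j], b[j + 1L, ])
    }
  }
  b <- pmin(pmax(b, 0), config$height)
  new("LayerBoundarySet", boundaries = b, height = as.numeric(config$height))
}

#' Render a phantom B-scan from boundary curves
#'
#' The mask assigns pixel `(r, x)` the label of the band whose half-open
#' interval `[boundary_j(x), boundary_{j+1}(x))` contains the pixel centre
#' `r - 0.5`, and background elsewhere.  The image composites the per-layer
#' reflectances, applies multiplicative speckle
#' `I * (1 + speckleLevel * N(0,1))` and clips to \[0,1\].
#'
#' @param boundaries A [LayerBoundarySet-class].
#' @param config The [phantomConfig()] that produced it.
#' @param rngSeed Seed for the speckle noise.
#' @return An [AnnotatedBScan-class].
#' @export
renderBScan <- function(boundaries, config, rngSeed = config$seed) {
  stopifnot(is(boundaries, "LayerBoundarySet"), inherits(config, "phantomConfig"))
  b <- boundaries@boundaries
  H <- config$height; W <- config$width; n <- config$nLayers
  centres <- seq_len(H) - 0.5
  cnt <- matrix(0L, H, W)
  for (j in seq_len(n + 1L))
    cnt <- cnt + outer(centres, b[j, ], ">=")
  mask <- ifelse(cnt >= 1L & cnt <= n, cnt, 0L)
  lut <- c(config$backgroundIntensity, config$layerIntensities)
  img <- matrix(lut[mask + 1L], H, W)
  if (config$speckleLevel > 0) {
    set.seed(rngSeed)
    img <- img * (1 + config$speckleLevel * stats::rnorm(H * W))
  }
  img <- pmin(pmax(img, 0), 1)
  AnnotatedBScan(image = img, mask = mask)
}

#' Generate a phantom dataset with a train/val/test split
#'
#' Draws `n` phantoms with per-image seeds derived from the master seed and
#' splits them in the 126:40:40 proportions of the annotated dataset (every
#' split non-empty).
#'
#' @param config A [phantomConfig()].
#' @param n Number of phantoms (>= 3, so all three splits are non-empty).
#' @param seed Master seed; the same `(config, seed)` pair reproduces the
#'   dataset exactly.
#' @return A list with `scans` (named list of [AnnotatedBScan-class]) and
#'   `split` (a [SplitSpec-class]).
#' @export
generatePhantoms <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "phantomConfig"))
  n <- as.integer(n)
  if (n < 3L) stop("need n >= 3 images to form three non-empty splits")
  ids <- sprintf("phantom_%03d", seq_len(n))
  scans <- vector("list", n)
  names(scans) <- ids
  for (i in seq_len(n)) {
    bset <- sampleBoundaries(config, rngSeed = seed + 2L * i)
    scans[[i]] <- renderBScan(bset, config, rngSeed = seed + 2L * i + 1L)
  }
  nVal <- max(1L, as.integer(round(n * 40 / 206)))
  nTest <- max(1L, as.integer(round(n * 40 / 206)))
  nTrain <- n - nVal - nTest
  split <- SplitSpec(train = ids[seq_len(nTrain)],
                     val = ids[nTrain + seq_len(nVal)],
                     test = ids[nTrain + nVal + seq_len(nTest)])
  list(scans = scans, split = split)
}
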