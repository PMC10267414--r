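# Shared fixtures: compact network configurations, small phantom sets and a
# memoized overfitted model reused by the interpretation tests.

tinyNetConfig <- function(...) {
  networkConfig(stageWidths = c(8L, 16L, 32L, 64L),
                stageDepths = c(1L, 1L, 1L, 1L),
                layerScale = 0.1, ...)
}

microNetConfig <- function(...) {
  networkConfig(stageWidths = c(4L, 8L, 16L, 32L),
                stageDepths = c(1L, 1L, 1L, 1L),
                camReduction = 2L, layerScale = 0.1, ...)
}

mildAugmentation <- function() {
  augmentationConfig(hflipProbability = 0.5, rotationRange = 0,
                     blurSigmaRange = c(0, 0), contrastRange = c(0.95, 1.05))
}

randomMask <- function(H, W, C, seed) {
  set.seed(seed)
  matrix(sample.int(C, H * W, replace = TRUE) - 1L, H, W)
}

.fixtureEnv <- new.env(parent = emptyenv())

# A micro model overfitted on one single-band phantom (class 1 band on
# background), shared across interpretation tests.
overfitBandModel <- function() {
  if (!is.null(.fixtureEnv$bandModel)) return(.fixtureEnv$bandModel)
  cfg <- phantomConfig(height = 32L, width = 48L, nLayers = 1L,
                       meanThickness = 8, boundaryAmplitude = 1,
                       boundaryWavelength = 32, pitDepth = 0, pitWidth = 8,
                       layerIntensities = 0.8, backgroundIntensity = 0.05,
                       speckleLevel = 0.05, topMargin = 10, seed = 4L)
  scan <- renderBScan(sampleBoundaries(cfg, 4L), cfg, 5L)
  net <- microNetConfig(nClasses = 2L)
  tc <- trainConfig(learningRate = 0.005, maxEpochs = 40L, batchSize = 1L,
                    steplrStep = 50L, seed = 2L, augment = NULL)
  st <- trainFold(list(scan), list(scan), net, tc)
  .fixtureEnv$bandModel <- list(model = st$bestModel, scan = scan, state = st)
  .fixtureEnv$bandModel
}
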