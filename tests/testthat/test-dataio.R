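# Palette mask encoding, augmentation, crops/pads, folds and file I/O.

test_that("palette decode handles background and single-layer rows", {
  pal <- defaultPalette()
  black <- array(0, c(4L, 5L, 3L))
  expect_equal(decodeMask(black, pal), matrix(0L, 4L, 5L))
  withRed <- black
  withRed[2L, , 1L] <- 1                  # one pure red row -> NFL (class 1)
  lab <- decodeMask(withRed, pal)
  expect_true(all(lab[2L, ] == 1L))
  expect_true(all(lab[-2L, ] == 0L))
})

test_that("unknown colors raise an error naming color and pixel", {
  bad <- array(0, c(3L, 3L, 3L))
  bad[2L, 3L, ] <- c(10, 20, 30) / 255
  expect_error(decodeMask(bad), "\\(10, 20, 30\\).*\\(2, 3\\)")
})

test_that("palette encode/decode round-trips random masks pixel-exactly", {
  pal <- defaultPalette()
  for (s in 1:100) {
    m <- randomMask(12L, 17L, nClasses(pal), seed = s)
    expect_identical(decodeMask(encodeMask(m, pal), pal), m)
  }
})

test_that("identity augmentation configuration is a no-op", {
  cfg <- cropPhantomConfig(32L, 48L)
  scan <- renderBScan(sampleBoundaries(cfg, 1L), cfg, 2L)
  out <- augmentSample(scan, identityAugmentation(), rngSeed = 3L)
  expect_identical(scanImage(out), scanImage(scan))
  expect_identical(scanMask(out), scanMask(scan))
})

test_that("forced horizontal flip is an involution and moves classes exactly", {
  flipOnly <- augmentationConfig(hflipProbability = 1, rotationRange = 0,
                                 blurSigmaRange = c(0, 0), contrastRange = c(1, 1))
  mask <- matrix(0L, 8L, 10L)
  mask[3:5, 1:4] <- 3L                     # class 3 only in the left half
  scan <- AnnotatedBScan(image = matrix(stats::runif(80), 8L), mask = mask)
  once <- augmentSample(scan, flipOnly, rngSeed = 1L)
  expect_equal(sum(scanMask(once) == 3L), sum(mask == 3L))
  expect_true(all(which(colSums(scanMask(once) == 3L) > 0) > 5L))
  twice <- augmentSample(once, flipOnly, rngSeed = 2L)
  expect_identical(scanImage(twice), scanImage(scan))
  expect_identical(scanMask(twice), scanMask(scan))
})

test_that("augmentation preserves shape and never invents labels", {
  cfg <- cropPhantomConfig(32L, 48L)
  scan <- renderBScan(sampleBoundaries(cfg, 5L), cfg, 6L)
  aug <- augmentationConfig(hflipProbability = 0.5, rotationRange = 10,
                            blurSigmaRange = c(0.2, 1.0),
                            contrastRange = c(0.8, 1.2))
  for (s in 1:8) {
    out <- augmentSample(scan, aug, rngSeed = s)
    expect_identical(dim(scanImage(out)), dim(scanImage(scan)))
    expect_identical(dim(scanMask(out)), dim(scanMask(scan)))
    expect_true(all(unique(as.integer(scanMask(out))) %in%
                      c(0L, unique(as.integer(scanMask(scan))))))
  }
})

test_that("rotation applies the same geometry to image and mask", {
  # a noiseless band phantom: rotated mask must still exactly track the
  # rotated image intensities
  cfg <- phantomConfig(height = 40L, width = 40L, nLayers = 2L,
                       meanThickness = 6, boundaryAmplitude = 0, pitDepth = 0,
                       layerIntensities = c(0.4, 0.9), speckleLevel = 0,
                       topMargin = 10)
  scan <- renderBScan(sampleBoundaries(cfg, 1L), cfg)
  rotOnly <- augmentationConfig(hflipProbability = 0, rotationRange = 15,
                                blurSigmaRange = c(0, 0), contrastRange = c(1, 1))
  out <- augmentSample(scan, rotOnly, rngSeed = 11L)
  # interior pixels (away from interpolated boundaries) of class 2 keep its
  # reflectance
  core <- scanImage(out)[scanMask(out) == 2L]
  expect_gt(mean(abs(core - 0.9) < 0.25), 0.9)
})

test_that("cropOrPad crops centrally and pads with background", {
  img <- matrix(stats::runif(500 * 750), 500L, 750L)
  mask <- randomMask(500L, 750L, 9L, seed = 1L)
  scan <- AnnotatedBScan(img, mask)
  out <- cropOrPad(scan, c(480L, 736L))
  expect_identical(dim(scanImage(out)), c(480L, 736L))
  expect_identical(scanImage(out), img[11:490, 8:743])
  expect_identical(scanMask(out), mask[11:490, 8:743])

  expect_identical(scanImage(cropOrPad(scan, c(500L, 750L))), img)

  small <- AnnotatedBScan(matrix(stats::runif(100), 10L), randomMask(10L, 10L, 3L, 2L))
  pad <- cropOrPad(small, c(12L, 12L))
  expect_identical(dim(scanImage(pad)), c(12L, 12L))
  expect_equal(sum(scanImage(pad)), sum(scanImage(small)))
  expect_true(all(scanImage(pad)[c(1L, 12L), ] == 0))
  expect_true(all(scanMask(pad)[, c(1L, 12L)] == 0L))
})

test_that("k-fold splits are balanced, disjoint and reproducible", {
  ids <- sprintf("s%03d", 1:126)
  folds <- makeFolds(ids, 4L, seed = 3L)
  sizes <- sort(vapply(folds, function(f) length(valIds(f)), integer(1)))
  expect_equal(sizes, c(31L, 31L, 32L, 32L))
  # validation lists partition the id set
  allVal <- unlist(lapply(folds, valIds))
  expect_setequal(allVal, ids)
  expect_equal(anyDuplicated(allVal), 0L)
  for (f in folds) {
    expect_setequal(c(trainIds(f), valIds(f)), ids)
    expect_length(intersect(trainIds(f), valIds(f)), 0L)
  }
  expect_identical(lapply(makeFolds(ids, 4L, seed = 3L), valIds),
                   lapply(folds, valIds))
  # leave-one-out
  loo <- makeFolds(ids[1:5], 5L, seed = 1L)
  expect_true(all(vapply(loo, function(f) length(valIds(f)), integer(1)) == 1L))
  expect_error(makeFolds(ids[1:3], 4L), "cannot form")
})

test_that("scan pairs and manifests round-trip through disk", {
  cfg <- cropPhantomConfig(32L, 48L)
  scan <- renderBScan(sampleBoundaries(cfg, 1L), cfg, 2L)
  td <- withr::local_tempdir()
  ip <- file.path(td, "img.png"); mp <- file.path(td, "mask.png")
  writeScanPair(scan, ip, mp)
  back <- readScanPair(ip, mp)
  expect_identical(scanMask(back), scanMask(scan))
  expect_lt(max(abs(scanImage(back) - scanImage(scan))), 1 / 255)

  mf <- data.frame(split = c("train", "val"), image = c("a.png", "b.png"),
                   mask = c("a_m.png", "b_m.png"))
  writeManifest(mf, file.path(td, "manifest.txt"))
  expect_equal(readManifest(file.path(td, "manifest.txt")), mf)
})
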