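# Attention algebra, architecture shape contracts, parameter accounting and
# basic learnability of the segmentation network.

test_that("zero-weight attention maps are 0.5 everywhere and CBAM scales by 0.25", {
  f <- array(stats::rnorm(4 * 6 * 8), c(6L, 8L, 4L))
  camW <- channelAttentionInit(4L, reduction = 2L, sd = 0)
  ca <- channelAttention(f, camW)
  expect_equal(ca$map, rep(0.5, 4L))
  samW <- spatialAttentionInit(7L, sd = 0)
  sa <- spatialAttention(f, samW)
  expect_true(all(sa$map == 0.5))
  cb <- cbamApply(f, cbamInitWeights(4L, reduction = 2L, sd = 0))
  expect_identical(cb$refined, 0.25 * f)
  # zero input stays zero regardless of the weights
  z <- array(0, c(6L, 8L, 4L))
  wb <- cbamInitWeights(4L, reduction = 2L, sd = 0.5, seed = 1L)
  expect_true(all(cbamApply(z, wb)$refined == 0))
})

test_that("channel attention pooling degenerates as expected", {
  # per-channel-constant map: avg pool equals max pool, Mc = sigmoid(2 MLP(s))
  f <- array(rep(c(1, -2, 0.5, 3), each = 20L), c(4L, 5L, 4L))
  w <- channelAttentionInit(4L, reduction = 2L, sd = 0.4, seed = 2L)
  ca <- channelAttention(f, w)
  expect_equal(ca$avg, ca$max)
  mlp <- function(s) {
    h <- pmax(drop(s %*% w$W1) + w$b1, 0)
    drop(h %*% w$W2) + w$b2
  }
  expect_equal(ca$map, 1 / (1 + exp(-2 * mlp(ca$avg))), tolerance = 1e-12)
  # single-channel input: channel-avg and channel-max both equal the map
  f1 <- array(stats::rnorm(30), c(5L, 6L, 1L))
  sa <- spatialAttention(f1, spatialAttentionInit(3L, sd = 0.3, seed = 3L))
  expect_equal(sa$avg, f1[, , 1L])
  expect_equal(sa$max, f1[, , 1L])
})

test_that("channel and spatial attention match hand-rolled oracles", {
  set.seed(7)
  f <- array(stats::rnorm(4 * 5 * 5), c(5L, 5L, 4L))
  w <- channelAttentionInit(4L, reduction = 2L, sd = 0.5, seed = 8L)
  ca <- channelAttention(f, w)
  # oracle: explicit pooling + affine + sigmoid
  savg <- apply(f, 3L, mean)
  smax <- apply(f, 3L, max)
  mlp <- function(s) drop(pmax(drop(s %*% w$W1) + w$b1, 0) %*% w$W2) + w$b2
  mc <- 1 / (1 + exp(-(mlp(savg) + mlp(smax))))
  expect_equal(ca$map, mc, tolerance = 1e-6)
  expect_equal(ca$refined, sweep(f, 3L, mc, "*"), tolerance = 1e-6)

  ws <- spatialAttentionInit(3L, sd = 0.5, seed = 9L)
  sa <- spatialAttention(array(stats::rnorm(3 * 9 * 9), c(9L, 9L, 3L)), ws)
  # oracle: direct 2-channel correlation of [avg; max] with the 3x3 kernel
  fa <- sa$avg; fm <- sa$max
  kern <- array(0, c(3L, 3L, 2L))
  for (j in 1:9) for (cc in 1:2) {
    i <- (j - 1L) %% 3L + 1L; jj <- (j - 1L) %/% 3L + 1L
    kern[i, jj, cc] <- ws$W[(j - 1L) * 2L + cc, 1L]
  }
  z <- directConv(array(c(fa, fm), c(9L, 9L, 2L)), kern) + ws$b
  expect_equal(sa$map, 1 / (1 + exp(-z)), tolerance = 1e-6)
})

test_that("CBAM equals the sequential channel-then-spatial composition", {
  for (s in 1:20) {
    set.seed(s)
    f <- array(stats::rnorm(3 * 6 * 7), c(6L, 7L, 3L))
    w <- cbamInitWeights(3L, reduction = 2L, samKernel = 3L, sd = 0.4, seed = 100L + s)
    cb <- cbamApply(f, w)
    step1 <- channelAttention(f, w$cam)$refined
    sam <- spatialAttention(step1, w$sam)
    expect_equal(cb$refined, sam$refined, tolerance = 1e-12)
    expect_true(all(cb$mc > 0 & cb$mc < 1))
    expect_true(all(cb$ms > 0 & cb$ms < 1))
  }
})

test_that("DE-CBAM halves channels, preserves spatial size and zero-propagates", {
  w <- deCbamInitWeights(8L, reduction = 2L, samKernel = 3L, sd = 0.3, seed = 4L)
  f <- array(stats::rnorm(8 * 16 * 16), c(16L, 16L, 8L))
  g <- deCbamApply(f, w)
  expect_identical(dim(g), c(16L, 16L, 8L %/% 2L))
  expect_error(deCbamInitWeights(7L), "even")
  # zero input with zero biases/shifts propagates to zero
  z <- deCbamApply(array(0, c(16L, 16L, 8L)), w)
  expect_true(all(z == 0))
})

test_that("the plain-CBAM projection variant has strictly fewer parameters", {
  ns <- asNamespace("octlayers")
  C <- 16L
  de <- ns$paramCount(ns$deCbamInit(C, 2L, 7L, 3L, sd = 0))
  pr <- ns$paramCount(ns$cbamProjInit(C, 2L, 7L, sd = 0))
  expect_lt(pr, de)
  # independent arithmetic for the difference: two separable convolutions
  # (dw 3x3 + bias, pw + bias, LN) versus one 1x1 projection
  sep <- (9 * C + C) + (C * C / 2 + C / 2) + C +
    (9 * C / 2 + C / 2) + (C / 2 * C / 2 + C / 2) + C
  proj <- C * C / 2 + C / 2
  expect_equal(de - pr, sep - proj)
})

test_that("the encoder pyramid follows the 1, 1/2, 1/4, 1/8 scale contract", {
  m <- buildNetwork(tinyNetConfig(), seed = 1L)
  img <- matrix(stats::runif(64 * 96), 64L, 96L)
  fp <- encodeFeatures(m, img)
  dims <- lapply(pyramidMaps(fp), dim)
  expect_equal(dims[[1L]][1:2], c(64L, 96L))
  expect_equal(dims[[2L]][1:2], c(32L, 48L))
  expect_equal(dims[[3L]][1:2], c(16L, 24L))
  expect_equal(dims[[4L]][1:2], c(8L, 12L))
  expect_equal(vapply(dims, `[`, integer(1), 3L), c(8L, 16L, 32L, 64L))
  # minimal divisible input: 8 -> 4 -> 2 -> 1 per side
  m8 <- buildNetwork(microNetConfig(), seed = 1L)
  d8 <- lapply(pyramidMaps(encodeFeatures(m8, matrix(0.5, 8L, 8L))), dim)
  expect_equal(vapply(d8, `[`, integer(1), 1L), c(8L, 4L, 2L, 1L))
  # the published deepest width: 128 channels at 1/8 resolution
  m128 <- buildNetwork(networkConfig(stageWidths = c(16L, 32L, 64L, 128L),
                                     stageDepths = c(1L, 1L, 1L, 1L)), seed = 1L)
  d128 <- dim(pyramidMaps(encodeFeatures(m128, matrix(0.5, 16L, 16L)))[[4L]])
  expect_equal(d128[3L], 128L)
  expect_error(encodeFeatures(m, matrix(0, 63L, 96L)), "cropOrPad")
})

test_that("decoder restores full resolution and its channel arithmetic holds", {
  cfg <- tinyNetConfig()
  expect_equal(cfg$decoderIn[1L], cfg$stageWidths[3L] + cfg$stageWidths[4L])
  expect_equal(cfg$decoderOut, cfg$decoderIn %/% 2L)
  expect_equal(cfg$decoderIn[2L], cfg$stageWidths[2L] + cfg$decoderOut[1L])
  m <- buildNetwork(cfg, seed = 2L)
  out <- networkForward(m, matrix(stats::runif(64 * 96), 64L, 96L))
  expect_identical(dim(out$logits), c(64L, 96L, 9L))
  # probabilities sum to 1 at every pixel
  expect_equal(apply(out$probs, c(1, 2), sum)[1:5, 1:5],
               matrix(1, 5L, 5L), tolerance = 1e-6)
  # minimal two-class toy configuration
  m2 <- buildNetwork(microNetConfig(nClasses = 2L), seed = 3L)
  expect_identical(dim(networkForward(m2, matrix(0.2, 8L, 8L))$logits),
                   c(8L, 8L, 2L))
  # odd concatenations are a configuration error at build time
  expect_error(networkConfig(stageWidths = c(5L, 8L, 16L, 32L)), "halved")
})

test_that("forward passes are deterministic and predict valid labels", {
  m <- buildNetwork(microNetConfig(), seed = 5L)
  img <- matrix(stats::runif(16 * 24), 16L, 24L)
  expect_identical(networkForward(m, img)$logits, networkForward(m, img)$logits)
  expect_identical(buildNetwork(microNetConfig(), seed = 5L)@params, m@params)
  pred <- predictMask(m, img)
  expect_true(all(pred >= 0L & pred <= 8L))
  expect_identical(dim(pred), dim(img))
})

test_that("parameter count equals an independent per-layer arithmetic sum", {
  cfg <- networkConfig(stageWidths = c(4L, 8L, 16L, 32L),
                       stageDepths = c(1L, 1L, 1L, 1L),
                       depthwiseKernel = 3L, samKernel = 3L,
                       decoderKernel = 3L, camReduction = 2L)
  w <- c(4, 8, 16, 32)
  block <- function(C) (9 * C + C) + 2 * C + (C * 4 * C + 4 * C) +
    (4 * C * C + C) + C
  down <- function(Ci, Co) 2 * Ci + (4 * Ci * Co + Co)
  cam <- function(C) { Ch <- C / 2; C * Ch + Ch + Ch * C + C }
  sam <- 9 * 2 + 1
  dwsep <- function(Ci, Co) (9 * Ci + Ci) + (Ci * Co + Co) + 2 * Co
  deCbam <- function(C) cam(C) + sam + dwsep(C, C / 2) + dwsep(C / 2, C / 2)
  decIn <- c(w[3] + w[4], 0, 0)
  decIn[2] <- w[2] + decIn[1] / 2
  decIn[3] <- w[1] + decIn[2] / 2
  expected <- (16 * w[1] + w[1]) + 2 * w[1] +          # stem conv + LN
    block(w[1]) + down(w[1], w[2]) + block(w[2]) +
    down(w[2], w[3]) + block(w[3]) + down(w[3], w[4]) + block(w[4]) +
    sum(vapply(decIn, deCbam, numeric(1))) +
    (decIn[3] / 2 * 9 + 9)                             # output 1x1 conv
  expect_equal(countParameters(cfg), expected)
  # doubling all widths grows a conv-dominated count by a factor in (2, 4]
  cfg2 <- networkConfig(stageWidths = 2L * c(4L, 8L, 16L, 32L),
                        stageDepths = c(1L, 1L, 1L, 1L),
                        depthwiseKernel = 3L, samKernel = 3L,
                        decoderKernel = 3L, camReduction = 2L)
  ratio <- countParameters(cfg2) / countParameters(cfg)
  expect_gt(ratio, 2)
  expect_lte(ratio, 4)
  expect_gt(countParameters(microNetConfig()), 0)
})

test_that("one optimization step gives every parameter group a gradient", {
  ns <- asNamespace("octlayers")
  cfg <- microNetConfig()
  m <- buildNetwork(cfg, seed = 6L)
  img <- matrix(stats::runif(16 * 24), 16L, 24L)
  target <- randomMask(16L, 24L, 9L, seed = 7L)
  fw <- ns$netForward(m@params, m@config, img, keepCache = TRUE)
  lg <- ns$ceLossGrad(fw$logits, as.integer(target))
  bw <- ns$netBackward(m@params, m@config, fw$cache, lg$dlogits)
  norms <- unlist(ns$mapNested(function(g) sqrt(sum(g * g)), bw$grads))
  expect_true(all(norms > 0))
})

test_that("the network can overfit a single phantom", {
  fx <- overfitBandModel()
  pred <- predictMask(fx$model, scanImage(fx$scan))
  acc <- mean(pred == scanMask(fx$scan))
  expect_gt(acc, 0.99)
})

test_that("checkpoints round-trip through disk with identical predictions", {
  m <- buildNetwork(microNetConfig(), seed = 8L)
  td <- withr::local_tempdir()
  saveModel(m, file.path(td, "m.json"))
  m2 <- loadModel(file.path(td, "m.json"))
  img <- matrix(stats::runif(16 * 16), 16L, 16L)
  expect_equal(networkForward(m2, img)$logits, networkForward(m, img)$logits,
               tolerance = 1e-12)
})

test_that("the transposed-convolution upsampling variant keeps the shape contract", {
  m <- buildNetwork(microNetConfig(upsampleMode = "transposed"), seed = 9L)
  out <- networkForward(m, matrix(stats::runif(16 * 24), 16L, 24L))
  expect_identical(dim(out$logits), c(16L, 24L, 9L))
})
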