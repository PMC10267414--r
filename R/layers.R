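# Attention modules (channel, spatial, CBAM, DE-CBAM) and ConvNeXt-style
# encoder blocks, each as an init / forward / backward triple over the
# (H*W) x C feature-matrix representation, plus exported array-level wrappers.

## ---- channel attention (CAM) ---------------------------------------------
# Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F))), shared one-hidden-layer MLP
# with C/r units; the map gates each channel.

camInit <- function(C, reduction = 16L, sd = NULL) {
  rEff <- max(1L, min(as.integer(reduction), C %/% 2L))
  Ch <- max(1L, C %/% rEff)
  sd1 <- if (is.null(sd)) heSd(C) else sd
  sd2 <- if (is.null(sd)) heSd(Ch) else sd
  list(W1 = matrix(stats::rnorm(C * Ch, 0, sd1), C, Ch), b1 = numeric(Ch),
       W2 = matrix(stats::rnorm(Ch * C, 0, sd2), Ch, C), b2 = numeric(C))
}

camForward <- function(p, x, keepCache = TRUE) {
  n <- nrow(x); C <- ncol(x)
  savg <- colMeans(x)
  imax <- max.col(t(x), ties.method = "first")
  smax <- x[cbind(imax, seq_len(C))]
  preA <- drop(savg %*% p$W1) + p$b1
  hA <- pmax(preA, 0)
  preM <- drop(smax %*% p$W1) + p$b1
  hM <- pmax(preM, 0)
  z <- drop(hA %*% p$W2) + drop(hM %*% p$W2) + 2 * p$b2
  mc <- sigmoid(z)
  y <- x * rep(mc, each = n)
  cache <- if (keepCache)
    list(x = x, savg = savg, smax = smax, imax = imax,
         hA = hA, hM = hM, mc = mc) else NULL
  list(y = y, mc = mc, savg = savg, smax = smax, cache = cache)
}

camBackward <- function(p, cache, dy) {
  x <- cache$x; mc <- cache$mc
  n <- nrow(x); C <- ncol(x)
  dmc <- colSums(x * dy)
  dx <- dy * rep(mc, each = n)
  dz <- dmc * mc * (1 - mc)
  db2 <- 2 * dz
  branch <- function(h, s) {
    dh <- drop(dz %*% t(p$W2)) * (h > 0)
    list(dW2 = outer(h, dz), dW1 = outer(s, dh), db1 = dh,
         ds = drop(dh %*% t(p$W1)))
  }
  bA <- branch(cache$hA, cache$savg)
  bM <- branch(cache$hM, cache$smax)
  dx <- dx + rep(bA$ds / n, each = n)
  dx[cbind(cache$imax, seq_len(C))] <- dx[cbind(cache$imax, seq_len(C))] + bM$ds
  list(dx = dx,
       grads = list(W1 = bA$dW1 + bM$dW1, b1 = bA$db1 + bM$db1,
                    W2 = bA$dW2 + bM$dW2, b2 = db2))
}

## ---- spatial attention (SAM) ---------------------------------------------
# Ms = sigmoid(conv7x7([channel-avg; channel-max])), gating every pixel.

samInit <- function(kernel = 7L, sd = NULL) {
  stopifnot(kernel %% 2L == 1L)
  c(convInit(2L, 1L, kernel, sd = sd), list(k = as.integer(kernel)))
}

samForward <- function(p, x, H, W, keepCache = TRUE) {
  n <- nrow(x); C <- ncol(x)
  a <- rowMeans(x)
  jmax <- max.col(x, ties.method = "first")
  m <- x[cbind(seq_len(n), jmax)]
  g <- convGeometry(H, W, p$k)
  cv <- convForward(p, cbind(a, m), g, 2L, keepCache = keepCache)
  s <- sigmoid(drop(cv$y))
  y <- x * s
  cache <- if (keepCache) list(x = x, jmax = jmax, s = s, conv = cv$cache) else NULL
  list(y = y, ms = s, cache = cache)
}

samBackward <- function(p, cache, dy) {
  x <- cache$x; s <- cache$s
  n <- nrow(x); C <- ncol(x)
  ds <- rowSums(x * dy)
  dx <- dy * s
  dz <- matrix(ds * s * (1 - s), n, 1L)
  cb <- convBackward(p, cache$conv, dz)
  da <- cb$dx[, 1L]; dm <- cb$dx[, 2L]
  dx <- dx + da / C
  dx[cbind(seq_len(n), cache$jmax)] <- dx[cbind(seq_len(n), cache$jmax)] + dm
  list(dx = dx, grads = list(W = cb$grads$W, b = cb$grads$b))
}

## ---- CBAM -----------------------------------------------------------------

cbamInit <- function(C, reduction = 16L, samKernel = 7L, sd = NULL) {
  list(cam = camInit(C, reduction, sd = sd), sam = samInit(samKernel, sd = sd))
}

cbamForward <- function(p, x, H, W, keepCache = TRUE) {
  ca <- camForward(p$cam, x, keepCache = keepCache)
  sa <- samForward(p$sam, ca$y, H, W, keepCache = keepCache)
  list(y = sa$y, mc = ca$mc, ms = sa$ms,
       cache = if (keepCache) list(cam = ca$cache, sam = sa$cache) else NULL)
}

cbamBackward <- function(p, cache, dy) {
  sb <- samBackward(p$sam, cache$sam, dy)
  cb <- camBackward(p$cam, cache$cam, sb$dx)
  list(dx = cb$dx, grads = list(cam = cb$grads, sam = sb$grads))
}

## ---- depthwise-separable conv stage (k x k depthwise + 1x1 pointwise,
##       layer norm, GELU) ---------------------------------------------------

dwsepInit <- function(Cin, Cout, k = 3L, sd = NULL) {
  sdp <- if (is.null(sd)) heSd(Cin) else sd
  list(dw = dwInit(Cin, k, sd = sd),
       pw = list(W = matrix(stats::rnorm(Cin * Cout, 0, sdp), Cin, Cout),
                 b = numeric(Cout)),
       ln = lnInit(Cout), k = as.integer(k))
}

dwsepForward <- function(p, x, H, W, keepCache = TRUE) {
  g <- convGeometry(H, W, p$k)
  d <- dwForward(p$dw, x, g, keepCache = keepCache)
  z <- d$y %*% p$pw$W
  z <- z + rep(p$pw$b, each = nrow(z))
  l <- lnForward(p$ln, z, keepCache = keepCache)
  a <- geluForward(l$y, keepCache = keepCache)
  cache <- if (keepCache) list(dw = d$cache, dwy = d$y, ln = l$cache, gelu = a$cache) else NULL
  list(y = a$y, cache = cache)
}

dwsepBackward <- function(p, cache, dy) {
  dl <- geluBackward(cache$gelu, dy)
  lb <- lnBackward(p$ln, cache$ln, dl)
  dz <- lb$dx
  dWpw <- crossprod(cache$dwy, dz)
  dbpw <- colSums(dz)
  ddwy <- dz %*% t(p$pw$W)
  db <- dwBackward(p$dw, cache$dw, ddwy)
  list(dx = db$dx,
       grads = list(dw = db$grads, pw = list(W = dWpw, b = dbpw), ln = lb$grads))
}

## ---- decoder attention blocks --------------------------------------------
# DE-CBAM: CBAM kept intact, then two consecutive depthwise-separable
# convolutions; the first pointwise stage halves the channel count, the
# second preserves it.  The plain-CBAM ablation variant replaces the two
# separable convolutions with a single 1x1 projection to half the channels.

deCbamInit <- function(C, reduction = 16L, samKernel = 7L, decoderKernel = 3L, sd = NULL) {
  if (C %% 2L != 0L)
    stop("DE-CBAM requires an even channel count, got ", C)
  list(cbam = cbamInit(C, reduction, samKernel, sd = sd),
       sep1 = dwsepInit(C, C %/% 2L, decoderKernel, sd = sd),
       sep2 = dwsepInit(C %/% 2L, C %/% 2L, decoderKernel, sd = sd))
}

deCbamForward <- function(p, x, H, W, keepCache = TRUE) {
  cb <- cbamForward(p$cbam, x, H, W, keepCache = keepCache)
  s1 <- dwsepForward(p$sep1, cb$y, H, W, keepCache = keepCache)
  s2 <- dwsepForward(p$sep2, s1$y, H, W, keepCache = keepCache)
  cache <- if (keepCache) list(cbam = cb$cache, sep1 = s1$cache, sep2 = s2$cache) else NULL
  list(y = s2$y, cache = cache)
}

deCbamBackward <- function(p, cache, dy) {
  s2 <- dwsepBackward(p$sep2, cache$sep2, dy)
  s1 <- dwsepBackward(p$sep1, cache$sep1, s2$dx)
  cb <- cbamBackward(p$cbam, cache$cbam, s1$dx)
  list(dx = cb$dx,
       grads = list(cbam = cb$grads, sep1 = s1$grads, sep2 = s2$grads))
}

cbamProjInit <- function(C, reduction = 16L, samKernel = 7L, sd = NULL) {
  if (C %% 2L != 0L)
    stop("the decoder attention block requires an even channel count, got ", C)
  sdp <- if (is.null(sd)) heSd(C) else sd
  list(cbam = cbamInit(C, reduction, samKernel, sd = sd),
       proj = list(W = matrix(stats::rnorm(C * (C %/% 2L), 0, sdp), C, C %/% 2L),
                   b = numeric(C %/% 2L)))
}

cbamProjForward <- function(p, x, H, W, keepCache = TRUE) {
  cb <- cbamForward(p$cbam, x, H, W, keepCache = keepCache)
  y <- cb$y %*% p$proj$W
  y <- y + rep(p$proj$b, each = nrow(y))
  list(y = y, cache = if (keepCache) list(cbam = cb$cache, cby = cb$y) else NULL)
}

cbamProjBackward <- function(p, cache, dy) {
  dW <- crossprod(cache$cby, dy)
  db <- colSums(dy)
  dcb <- dy %*% t(p$proj$W)
  cb <- cbamBackward(p$cbam, cache$cbam, dcb)
  list(dx = cb$dx, grads = list(cbam = cb$grads, proj = list(W = dW, b = db)))
}

## ---- ConvNeXt block -------------------------------------------------------
# 7x7 depthwise conv -> LayerNorm -> 1x1 expand (4C) -> GELU -> 1x1 project
# -> per-channel layer scale -> residual add.

cnxBlockInit <- function(C, k = 7L, sd = NULL, layerScale = 1e-6) {
  sd1 <- if (is.null(sd)) heSd(C) else sd
  sd2 <- if (is.null(sd)) heSd(4L * C) else sd
  list(dw = dwInit(C, k, sd = sd), ln = lnInit(C),
       pw1 = list(W = matrix(stats::rnorm(C * 4L * C, 0, sd1), C, 4L * C), b = numeric(4L * C)),
       pw2 = list(W = matrix(stats::rnorm(4L * C * C, 0, sd2), 4L * C, C), b = numeric(C)),
       ls = rep(layerScale, C), k = as.integer(k))
}

cnxBlockForward <- function(p, x, H, W, keepCache = TRUE) {
  n <- nrow(x)
  g <- convGeometry(H, W, p$k)
  d <- dwForward(p$dw, x, g, keepCache = keepCache)
  l <- lnForward(p$ln, d$y, keepCache = keepCache)
  z1 <- l$y %*% p$pw1$W
  z1 <- z1 + rep(p$pw1$b, each = n)
  a <- geluForward(z1, keepCache = keepCache)
  z2 <- a$y %*% p$pw2$W
  z2 <- z2 + rep(p$pw2$b, each = n)
  y <- x + z2 * rep(p$ls, each = n)
  cache <- if (keepCache)
    list(dw = d$cache, ln = l$cache, lny = l$y, gelu = a$cache, ay = a$y, z2 = z2) else NULL
  list(y = y, cache = cache)
}

cnxBlockBackward <- function(p, cache, dy) {
  n <- nrow(dy)
  dls <- colSums(dy * cache$z2)
  dz2 <- dy * rep(p$ls, each = n)
  dW2 <- crossprod(cache$ay, dz2)
  db2 <- colSums(dz2)
  da <- dz2 %*% t(p$pw2$W)
  dz1 <- geluBackward(cache$gelu, da)
  dW1 <- crossprod(cache$lny, dz1)
  db1 <- colSums(dz1)
  dln <- dz1 %*% t(p$pw1$W)
  lb <- lnBackward(p$ln, cache$ln, dln)
  db <- dwBackward(p$dw, cache$dw, lb$dx)
  dx <- dy + db$dx
  list(dx = dx,
       grads = list(dw = db$grads, ln = lb$grads,
                    pw1 = list(W = dW1, b = db1), pw2 = list(W = dW2, b = db2),
                    ls = dls))
}

## ---- exported array-level wrappers ---------------------------------------

#' Build channel-attention weights
#'
#' Initializes the shared two-layer perceptron of a channel attention module
#' for a feature map with `C` channels.  With `sd = 0` all weights are zero,
#' which is convenient for algebraic checks (the sigmoid of zero is 0.5).
#'
#' @param C Number of channels of the feature map the module will gate.
#' @param reduction Bottleneck ratio `r`; the hidden layer has `C/r` units.
#'   Automatically clamped to at most `C/2` for narrow maps.
#' @param sd Standard deviation of the normal weight initialization.
#' @param seed Optional RNG seed for reproducible initialization.
#' @return A list of weight matrices usable by [channelAttention()].
#' @export
channelAttentionInit <- function(C, reduction = 16L, sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  camInit(C, reduction, sd = sd)
}

#' Channel attention map
#'
#' Computes the one-dimensional channel attention map
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` of a feature map, where
#' the average and max pooling are global over the spatial extent and the
#' multilayer perceptron (one hidden layer of `C/r` units) is shared between
#' the two pooled descriptors, whose outputs are merged by elementwise
#' summation before the sigmoid.
#'
#' @param f Feature map as an `H x W x C` array (channels last).
#' @param weights Module weights from [channelAttentionInit()].
#' @return A list with `map` (length-`C` vector in (0,1)), the pooled
#'   descriptors `avg` and `max`, and `refined`, the gated feature map
#'   `Mc * F` with the map broadcast over the spatial extent.
#' @export
channelAttention <- function(f, weights) {
  x <- asFeatureMatrix(f)
  d <- dim(f)
  out <- camForward(weights, x, keepCache = FALSE)
  list(map = out$mc, avg = out$savg, max = out$smax,
       refined = asFeatureArray(out$y, d[1L], d[2L]))
}

#' Build spatial-attention weights
#'
#' @param kernel Odd convolution kernel size (7 in the published module).
#' @param sd Standard deviation of the weight initialization.
#' @param seed Optional RNG seed.
#' @return Weights usable by [spatialAttention()].
#' @export
spatialAttentionInit <- function(kernel = 7L, sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samInit(kernel, sd = sd)
}

#' Spatial attention map
#'
#' Computes the two-dimensional spatial attention map
#' `Ms = sigmoid(f_kxk([avgpool_c(F); maxpool_c(F)]))`: the feature map is
#' pooled across channels (average and maximum), the two maps are stacked and
#' convolved with a single `k x k` filter, and the sigmoid gates every pixel.
#'
#' @param f Feature map as an `H x W x C` array.
#' @param weights Module weights from [spatialAttentionInit()].
#' @return A list with `map` (`H x W` matrix in (0,1)), the channel-pooled
#'   `avg` and `max` maps, and the gated feature map `refined`.
#' @export
spatialAttention <- function(f, weights) {
  d <- dim(f)
  x <- asFeatureMatrix(f)
  out <- samForward(weights, x, d[1L], d[2L], keepCache = FALSE)
  list(map = matrix(out$ms, d[1L], d[2L]),
       avg = matrix(rowMeans(x), d[1L], d[2L]),
       max = matrix(x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))],
                    d[1L], d[2L]),
       refined = asFeatureArray(out$y, d[1L], d[2L]))
}

#' Build CBAM weights
#'
#' @inheritParams channelAttentionInit
#' @param samKernel Spatial-attention kernel size.
#' @return Weights usable by [cbamApply()].
#' @export
cbamInitWeights <- function(C, reduction = 16L, samKernel = 7L, sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbamInit(C, reduction, samKernel, sd = sd)
}

#' Apply a convolutional block attention module
#'
#' Sequential channel-then-spatial attention: `F' = Mc(F) * F` followed by
#' `F'' = Ms(F') * F'`, each map broadcast over the dimensions it does not
#' index.  Shape is preserved.
#'
#' @param f Feature map as an `H x W x C` array.
#' @param weights Weights from [cbamInitWeights()].
#' @return A list with the refined map `refined` (same shape as `f`), the
#'   channel map `mc` and the spatial map `ms`.
#' @export
cbamApply <- function(f, weights) {
  d <- dim(f)
  out <- cbamForward(weights, asFeatureMatrix(f), d[1L], d[2L], keepCache = FALSE)
  list(refined = asFeatureArray(out$y, d[1L], d[2L]),
       mc = out$mc, ms = matrix(out$ms, d[1L], d[2L]))
}

#' Build DE-CBAM weights
#'
#' @inheritParams cbamInitWeights
#' @param decoderKernel Kernel size of the two depthwise-separable
#'   convolutions appended to the CBAM output.
#' @return Weights usable by [deCbamApply()].
#' @export
deCbamInitWeights <- function(C, reduction = 16L, samKernel = 7L,
                              decoderKernel = 3L, sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  deCbamInit(C, reduction, samKernel, decoderKernel, sd = sd)
}

#' Apply a depth-efficient CBAM block
#'
#' CBAM applied unchanged, followed by two consecutive depthwise-separable
#' convolutions (depthwise `k x k` plus pointwise 1x1, each with layer
#' normalization and GELU); the first pointwise stage halves the channel
#' count and the second preserves it, so a `C`-channel input yields a
#' `C/2`-channel output at the same spatial size.
#'
#' @param f Feature map as an `H x W x C` array with even `C`.
#' @param weights Weights from [deCbamInitWeights()].
#' @return The refined `H x W x C/2` array.
#' @export
deCbamApply <- function(f, weights) {
  d <- dim(f)
  out <- deCbamForward(weights, asFeatureMatrix(f), d[1L], d[2L], keepCache = FALSE)
  asFeatureArray(out$y, d[1L], d[2L])
}
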