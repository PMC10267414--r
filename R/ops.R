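# Internal numerical primitives for the segmentation network.
#
# A feature map is stored as an (H*W) x C numeric matrix, column-major over
# (H, W) with the row index varying fastest: pixel (r, c) lives at matrix row
# r + (c - 1) * H.  Pointwise (1x1) convolutions are then plain GEMMs; spatial
# convolutions go through im2col patch matrices; depthwise convolutions use
# shift-and-accumulate gathers.  Every forward has a matching backward used by
# the training loop and by the activation-heatmap gradients.

.geomCache <- new.env(parent = emptyenv())

# Gather geometry for a k x k convolution: for each kernel offset, the output
# pixels whose receptive field stays in frame and the matching input indices.
convGeometry <- function(H, W, k, stride = 1L,
                         padTop = (k - 1L) %/% 2L, padLeft = padTop,
                         padBottom = k - 1L - padTop, padRight = k - 1L - padLeft) {
  key <- paste("c", H, W, k, stride, padTop, padLeft, padBottom, padRight, sep = "_")
  g <- .geomCache[[key]]
  if (!is.null(g)) return(g)
  Ho <- (H + padTop + padBottom - k) %/% stride + 1L
  Wo <- (W + padLeft + padRight - k) %/% stride + 1L
  ro <- rep.int(seq_len(Ho), Wo)
  co <- rep(seq_len(Wo), each = Ho)
  offsets <- vector("list", k * k)
  n <- 1L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      ri <- (ro - 1L) * stride + i - padTop
      ci <- (co - 1L) * stride + j - padLeft
      ok <- ri >= 1L & ri <= H & ci >= 1L & ci <= W
      offsets[[n]] <- list(out = which(ok),
                           src = ri[ok] + (ci[ok] - 1L) * H)
      n <- n + 1L
    }
  }
  g <- list(H = H, W = W, Ho = Ho, Wo = Wo, k = k, stride = stride,
            offsets = offsets)
  .geomCache[[key]] <- g
  g
}

# Patch matrix (Ho*Wo) x (k*k*C); column block j holds the input values under
# kernel offset j (zeros where the padded field falls outside the frame).
im2col <- function(x, g, C) {
  P <- matrix(0, g$Ho * g$Wo, g$k * g$k * C)
  for (j in seq_along(g$offsets)) {
    o <- g$offsets[[j]]
    P[o$out, ((j - 1L) * C + 1L):(j * C)] <- x[o$src, , drop = FALSE]
  }
  P
}

col2im <- function(dP, g, C) {
  dx <- matrix(0, g$H * g$W, C)
  for (j in seq_along(g$offsets)) {
    o <- g$offsets[[j]]
    dx[o$src, ] <- dx[o$src, ] +
      dP[o$out, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dx
}

## ---- dense (full) convolution -------------------------------------------

# sd = NULL selects fan-in (He) scaling, the default for trained networks.
heSd <- function(fanIn) sqrt(2 / fanIn)

convInit <- function(Cin, Cout, k, sd = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sd)) sd <- heSd(k * k * Cin)
  W <- matrix(stats::rnorm(k * k * Cin * Cout, 0, sd), k * k * Cin, Cout)
  list(W = W, b = numeric(Cout))
}

convForward <- function(p, x, g, Cin, keepCache = TRUE) {
  P <- im2col(x, g, Cin)
  y <- P %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  list(y = y, cache = if (keepCache) list(P = P, g = g, Cin = Cin) else NULL)
}

convBackward <- function(p, cache, dy) {
  dW <- crossprod(cache$P, dy)
  db <- colSums(dy)
  dP <- dy %*% t(p$W)
  dx <- col2im(dP, cache$g, cache$Cin)
  list(dx = dx, grads = list(W = dW, b = db))
}

## ---- depthwise convolution ----------------------------------------------

dwInit <- function(C, k, sd = NULL) {
  if (is.null(sd)) sd <- heSd(k * k)
  list(W = matrix(stats::rnorm(k * k * C, 0, sd), k * k, C), b = numeric(C))
}

dwForward <- function(p, x, g, keepCache = TRUE) {
  C <- ncol(x)
  y <- matrix(rep(p$b, each = g$Ho * g$Wo), g$Ho * g$Wo, C)
  for (j in seq_along(g$offsets)) {
    o <- g$offsets[[j]]
    y[o$out, ] <- y[o$out, ] +
      x[o$src, , drop = FALSE] * rep(p$W[j, ], each = length(o$out))
  }
  list(y = y, cache = if (keepCache) list(x = x, g = g) else NULL)
}

dwBackward <- function(p, cache, dy) {
  x <- cache$x; g <- cache$g
  C <- ncol(x)
  dW <- matrix(0, nrow(p$W), C)
  dx <- matrix(0, nrow(x), C)
  for (j in seq_along(g$offsets)) {
    o <- g$offsets[[j]]
    xb <- x[o$src, , drop = FALSE]
    db <- dy[o$out, , drop = FALSE]
    dW[j, ] <- colSums(xb * db)
    dx[o$src, ] <- dx[o$src, ] + db * rep(p$W[j, ], each = length(o$out))
  }
  list(dx = dx, grads = list(W = dW, b = colSums(dy)))
}

## ---- 2x2 stride-2 transposed convolution (learned upsampling) -----------

tconvInit <- function(Cin, Cout, sd = NULL) {
  if (is.null(sd)) sd <- heSd(Cin)
  list(W = lapply(1:4, function(i) matrix(stats::rnorm(Cin * Cout, 0, sd), Cin, Cout)),
       b = numeric(Cout))
}

# Output pixel (2r-1+di, 2c-1+dj) receives x[r, c, ] %*% W[[pos]]; kernel
# positions never overlap for stride 2, so each is an independent GEMM.
tconvForward <- function(p, x, H, W, keepCache = TRUE) {
  Cout <- length(p$b)
  n <- H * W
  y <- matrix(rep(p$b, each = 4L * n), 4L * n, Cout)
  sel <- .tconvSel(H, W)
  for (t in 1:4) y[sel[[t]], ] <- y[sel[[t]], ] + x %*% p$W[[t]]
  list(y = y, cache = if (keepCache) list(x = x, sel = sel) else NULL)
}

tconvBackward <- function(p, cache, dy) {
  x <- cache$x; sel <- cache$sel
  dx <- matrix(0, nrow(x), nrow(p$W[[1]]))
  dW <- vector("list", 4)
  for (t in 1:4) {
    dyt <- dy[sel[[t]], , drop = FALSE]
    dW[[t]] <- crossprod(x, dyt)
    dx <- dx + dyt %*% t(p$W[[t]])
  }
  list(dx = dx, grads = list(W = dW, b = colSums(dy)))
}

.tconvSel <- function(H, W) {
  key <- paste("t", H, W, sep = "_")
  s <- .geomCache[[key]]
  if (!is.null(s)) return(s)
  r <- rep.int(seq_len(H), W); c <- rep(seq_len(W), each = H)
  Ho <- 2L * H
  s <- list()
  n <- 1L
  for (dj in 0:1) for (di in 0:1) {
    s[[n]] <- (2L * r - 1L + di) + (2L * c - 2L + dj) * Ho
    n <- n + 1L
  }
  .geomCache[[key]] <- s
  s
}

## ---- bilinear 2x upsampling ---------------------------------------------

upGeometry <- function(H, W) {
  key <- paste("u", H, W, sep = "_")
  g <- .geomCache[[key]]
  if (!is.null(g)) return(g)
  axis <- function(n) {
    s <- seq_len(2L * n) / 2 + 0.25        # source coordinate, 1-based centres
    lo <- floor(s)
    w <- s - lo
    l0 <- pmin(pmax(lo, 1), n)
    l1 <- pmin(lo + 1, n)
    list(l0 = as.integer(l0), l1 = as.integer(l1), w = w)
  }
  ar <- axis(H); ac <- axis(W)
  Ho <- 2L * H; Wo <- 2L * W
  rr0 <- rep.int(ar$l0, Wo); rr1 <- rep.int(ar$l1, Wo); wr <- rep.int(ar$w, Wo)
  cc0 <- rep(ac$l0, each = Ho); cc1 <- rep(ac$l1, each = Ho); wc <- rep(ac$w, each = Ho)
  g <- list(
    idx = list(rr0 + (cc0 - 1L) * H, rr1 + (cc0 - 1L) * H,
               rr0 + (cc1 - 1L) * H, rr1 + (cc1 - 1L) * H),
    w = list((1 - wr) * (1 - wc), wr * (1 - wc), (1 - wr) * wc, wr * wc),
    H = H, W = W)
  .geomCache[[key]] <- g
  g
}

upForward <- function(x, H, W) {
  g <- upGeometry(H, W)
  y <- 0
  for (t in 1:4) y <- y + x[g$idx[[t]], , drop = FALSE] * g$w[[t]]
  y
}

upBackward <- function(dy, H, W) {
  g <- upGeometry(H, W)
  dx <- matrix(0, H * W, ncol(dy))
  for (t in 1:4) {
    agg <- rowsum(dy * g$w[[t]], g$idx[[t]])
    rows <- as.integer(rownames(agg))
    dx[rows, ] <- dx[rows, ] + agg
  }
  dx
}

## ---- layer normalization over channels ----------------------------------

lnInit <- function(C) list(g = rep(1, C), b = numeric(C))

lnForward <- function(p, x, eps = 1e-6, keepCache = TRUE) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * rep(p$g, each = n) + rep(p$b, each = n)
  list(y = y, cache = if (keepCache) list(xhat = xhat, inv = inv) else NULL)
}

lnBackward <- function(p, cache, dy) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(p$g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, grads = list(g = dg, b = db))
}

## ---- elementwise nonlinearities ------------------------------------------

geluForward <- function(x, keepCache = TRUE) {
  ph <- stats::pnorm(x)
  list(y = x * ph, cache = if (keepCache) list(x = x, ph = ph) else NULL)
}

geluBackward <- function(cache, dy) {
  dy * (cache$ph + cache$x * stats::dnorm(cache$x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- softmax / cross-entropy ---------------------------------------------

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- misc helpers ---------------------------------------------------------

asFeatureMatrix <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) d <- c(d, 1L)
  matrix(a, d[1L] * d[2L], d[3L])
}

asFeatureArray <- function(m, H, W) array(m, c(H, W, ncol(m)))

# Recursive Map over parallel nested lists of numeric arrays.
mapNested <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1L]])) {
    out <- vector("list", length(xs[[1L]]))
    names(out) <- names(xs[[1L]])
    for (i in seq_along(out))
      out[[i]] <- do.call(mapNested, c(list(f), lapply(xs, `[[`, i)))
    out
  } else {
    do.call(f, xs)
  }
}

sumNested <- function(a, b) mapNested(`+`, a, b)

# Counts trainable numbers in a nested parameter list; entries named "k"
# are structural kernel sizes, not weights.
paramCount <- function(p) {
  if (is.list(p)) {
    keep <- if (is.null(names(p))) seq_along(p) else which(names(p) != "k")
    sum(vapply(p[keep], paramCount, numeric(1)))
  } else {
    length(p)
  }
}
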