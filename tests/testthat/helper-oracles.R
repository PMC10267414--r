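# Independent oracles: brute-force per-pixel metric counting, exhaustive
# rank-sum enumeration, and a direct correlation oracle for small
# convolutions.  These deliberately share no code with the implementation.

bruteMetrics <- function(pred, true, C) {
  p <- as.integer(pred); t <- as.integer(true)
  n <- length(p)
  tp <- fp <- fn <- tn <- numeric(C)
  for (c in 0:(C - 1L)) {
    for (i in seq_len(n)) {
      isP <- p[i] == c; isT <- t[i] == c
      if (isP && isT) tp[c + 1L] <- tp[c + 1L] + 1
      else if (isP && !isT) fp[c + 1L] <- fp[c + 1L] + 1
      else if (!isP && isT) fn[c + 1L] <- fn[c + 1L] + 1
      else tn[c + 1L] <- tn[c + 1L] + 1
    }
  }
  support <- tp + fp + fn
  dice <- 2 * tp / (2 * tp + fp + fn)
  iou <- tp / (tp + fp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       dice = dice, iou = iou,
       mIoU = mean(iou[support > 0]),
       acc = sum(tp) / n,
       mPA = mean((tp / (tp + fn))[support > 0 & (tp + fn) > 0]))
}

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled midranks to group A.
enumRankSumP <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  pLe <- mean(sums <= w + 1e-9)
  pGe <- mean(sums >= w - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

# Direct correlation of a multi-channel map with a dense kernel, zero
# padding, 'same' output; x is H x W x C, kern is k x k x C (summed over C).
directConv <- function(x, kern) {
  H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
  k <- dim(kern)[1L]
  pad <- (k - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    acc <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ri <- r + i - 1L - pad; ci <- cc + j - 1L - pad
      if (ri >= 1 && ri <= H && ci >= 1 && ci <= W)
        acc <- acc + sum(kern[i, j, ] * x[ri, ci, ])
    }
    out[r, cc] <- acc
  }
  out
}
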