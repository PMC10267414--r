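# Segmentation evaluation: one-vs-rest confusion counts, per-class Dice and
# IoU with the mIoU / Acc / mPA aggregates, rank-sum comparison of
# per-image scores between methods, and error distribution maps.

#' Per-class confusion counts
#'
#' One-vs-rest pixel tallies for every class.
#'
#' @slot tp,tn,fp,fn Numeric vectors of length C (class 0 first).
#' @export
setClass("ConfusionCounts",
         representation(tp = "numeric", tn = "numeric",
                        fp = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  n <- length(object@tp)
  if (any(c(length(object@tn), length(object@fp), length(object@fn)) != n))
    return("all four count vectors must have equal length")
  tot <- object@tp + object@tn + object@fp + object@fn
  if (n > 0 && max(abs(tot - tot[1L])) > 0)
    return("per-class counts must sum to the same pixel total")
  TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: %d classes, %g pixels, %.2f%% correct\n",
              length(object@tp), object@tp[1L] + object@tn[1L] +
                object@fp[1L] + object@fn[1L],
              100 * sum(object@tp) /
                (object@tp[1L] + object@tn[1L] + object@fp[1L] + object@fn[1L])))
})

#' Compute confusion counts from a mask pair
#'
#' @param pred,true Integer label matrices (or vectors) of equal shape with
#'   labels in `0..nClasses-1`.
#' @param nClasses Total number of classes C.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, true, nClasses) {
  if (!identical(dim(pred), dim(true)) || length(pred) != length(true))
    stop("pred and true must have identical shape")
  p <- as.integer(pred); t <- as.integer(true)
  if (min(p, t) < 0 || max(p, t) >= nClasses)
    stop(sprintf("labels must lie in 0..%d", nClasses - 1L))
  lv <- 0:(nClasses - 1L)
  tab <- table(factor(t, levels = lv), factor(p, levels = lv))
  tp <- as.numeric(diag(tab))
  fn <- as.numeric(rowSums(tab)) - tp
  fp <- as.numeric(colSums(tab)) - tp
  tn <- length(p) - tp - fp - fn
  new("ConfusionCounts", tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Segmentation metrics from confusion counts
#'
#' Per class `c`: `Dice_c = 2TP/(2TP+FP+FN)` and `IoU_c = TP/(TP+FP+FN)`.
#' Aggregates: `mIoU` is the mean IoU over all classes (background
#' included), `Acc = sum(TP) / total pixels` (micro accuracy), and `mPA`
#' the mean per-class pixel accuracy `TP/(TP+FN)`.  Classes absent from
#' both prediction and truth are excluded from the mIoU and mPA means.
#'
#' The conventional `mPA = mean TP/(TP+FN)` is the default; `formula =
#' "as-printed"` selects the alternative `mean TP/(TP+TN+FP+FN)` for
#' auditability (that variant approximates `Acc / C` rather than a
#' per-class accuracy).
#'
#' @param counts A [ConfusionCounts-class].
#' @param formula `"conventional"` or `"as-printed"` (see Details).
#' @return A list of class `"metricReport"`: `perClass` data frame (class,
#'   dice, iou, pixelAcc), `mIoU`, `acc`, `mPA`, `meanDice` (foreground
#'   mean Dice).
#' @export
computeMetrics <- function(counts, formula = c("conventional", "as-printed")) {
  formula <- match.arg(formula)
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  total <- tp[1L] + tn[1L] + fp[1L] + fn[1L]
  if (total == 0) stop("empty counts: metrics are undefined")
  support <- tp + fp + fn             # pixels of the class in either mask
  dice <- ifelse(support > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  iou <- ifelse(support > 0, tp / (tp + fp + fn), NA_real_)
  pa <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  mIoU <- mean(iou[support > 0])
  acc <- sum(tp) / total
  mPA <- if (formula == "conventional") {
    mean(pa[support > 0], na.rm = TRUE)
  } else {
    mean((tp / total)[support > 0])
  }
  fg <- support > 0 & seq_along(tp) > 1L
  structure(list(perClass = data.frame(class = seq_along(tp) - 1L,
                                       dice = dice, iou = iou, pixelAcc = pa),
                 mIoU = mIoU, acc = acc, mPA = mPA,
                 meanDice = mean(dice[fg])),
            class = "metricReport")
}

#' Render a metric value as a percentage string
#'
#' Rounds half away from zero to one decimal, matching the table formatting
#' convention (91.25 -> "91.3").
#'
#' @param x Numeric values in \[0, 1\].
#' @return Character vector of percentages with one decimal.
#' @export
formatPercent <- function(x) {
  sprintf("%.1f", sign(x) * floor(abs(x) * 1000 + 0.5) / 10)
}

#' Two-sided Wilcoxon rank-sum comparison of per-image scores
#'
#' Compares two sets of per-image scores (for example per-image Dice of two
#' segmentation methods) with the two-sample rank-sum (Mann-Whitney) test.
#' For sample sizes up to 25 per group the exact permutation distribution
#' of the rank sum is computed (ties handled exactly via midranks); larger
#' samples use the normal approximation with tie and continuity correction.
#'
#' @param a,b Non-empty numeric vectors of per-image scores.
#' @param exactLimit Largest per-group size for the exact distribution.
#' @return Two-sided p-value in (0, 1\]; identical pooled values return 1
#'   with a warning.
#' @export
compareMethods <- function(a, b, exactLimit = 25L) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both score vectors must be non-empty")
  pooled <- c(a, b)
  if (max(pooled) == min(pooled)) {
    warning("all pooled values are identical; returning p = 1")
    return(1)
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r2 <- as.integer(round(2 * rank(pooled)))   # doubled midranks are integers
  w <- sum(r2[seq_len(n1)])
  if (n1 <= exactLimit && n2 <= exactLimit) {
    # distribution of the (doubled) rank sum over all C(n, n1) assignments
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    ways <- matrix(0, n1 + 1L, smax + 1L)
    ways[1L, 1L] <- 1
    for (v in r2) {
      for (j in n1:1) {
        cols <- seq_len(smax + 1L - v)
        ways[j + 1L, cols + v] <- ways[j + 1L, cols + v] + ways[j, cols]
      }
    }
    dist <- ways[n1 + 1L, ]
    totalWays <- sum(dist)
    pLe <- sum(dist[seq_len(w + 1L)]) / totalWays
    pGe <- sum(dist[(w + 1L):(smax + 1L)]) / totalWays
    min(1, 2 * min(pLe, pGe))
  } else {
    u <- w / 2 - n1 * (n1 + 1) / 2          # Mann-Whitney U from the rank sum
    mu <- n1 * n2 / 2
    tie <- table(r2)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    z <- u - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Pixel error map between two masks
#'
#' @param pred,true Integer label matrices of equal shape.
#' @return A list with `map` (binary matrix, 1 where the labels disagree)
#'   and `fraction` (disagreement fraction, equal to `1 - Acc`).
#' @export
errorMap <- function(pred, true) {
  if (!identical(dim(pred), dim(true)))
    stop("pred and true must have identical shape")
  m <- (pred != true) * 1L
  list(map = m, fraction = mean(m))
}
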