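# Confusion counts, Dice/IoU/accuracy metrics, rank-sum comparison and
# error maps, each against independent oracles.

test_that("confusion counts match enumeration on toy masks", {
  true <- matrix(c(0L, 0L, 1L, 1L), 2L, 2L)
  pred <- matrix(c(0L, 1L, 1L, 1L), 2L, 2L)
  cc <- confusionCounts(pred, true, 2L)
  expect_equal(cc@tp[2L], 2)   # class 1: two hits
  expect_equal(cc@fp[2L], 1)
  expect_equal(cc@fn[2L], 0)
  expect_equal(cc@tn[2L], 1)
  # perfect prediction: no errors anywhere
  cp <- confusionCounts(true, true, 2L)
  expect_true(all(cp@fp == 0) && all(cp@fn == 0))
  # swapping the masks swaps FP and FN for every class
  sw <- confusionCounts(true, pred, 2L)
  expect_equal(sw@fp, cc@fn)
  expect_equal(sw@fn, cc@fp)
  expect_error(confusionCounts(pred, true[, 1L, drop = FALSE], 2L), "shape")
  expect_error(confusionCounts(pred + 5L, true, 2L), "labels")
})

test_that("metric formulas reproduce direct arithmetic", {
  # class with TP=6, FP=2, FN=2 among 20 pixels
  true <- c(rep(1L, 8L), rep(0L, 12L))
  pred <- c(rep(1L, 6L), 0L, 0L, rep(1L, 2L), rep(0L, 10L))
  m <- computeMetrics(confusionCounts(matrix(pred, 4L), matrix(true, 4L), 2L))
  expect_equal(m$perClass$dice[2L], 12 / 16)
  expect_equal(m$perClass$iou[2L], 6 / 10)
  # perfect prediction: everything is 1
  mp <- computeMetrics(confusionCounts(matrix(true, 4L), matrix(true, 4L), 2L))
  expect_equal(mp$perClass$dice, c(1, 1))
  expect_equal(c(mp$mIoU, mp$acc, mp$mPA), c(1, 1, 1))
  expect_error(computeMetrics(new("ConfusionCounts", tp = 0, tn = 0,
                                  fp = 0, fn = 0)), "undefined")
})

test_that("metrics agree with the brute-force counting oracle", {
  for (s in 1:25) {
    pred <- randomMask(20L, 20L, 4L, seed = 2 * s)
    true <- randomMask(20L, 20L, 4L, seed = 2 * s + 1L)
    cc <- confusionCounts(pred, true, 4L)
    m <- computeMetrics(cc)
    o <- bruteMetrics(pred, true, 4L)
    expect_equal(cc@tp, o$tp, tolerance = 1e-12)
    expect_equal(m$perClass$dice, o$dice, tolerance = 1e-12)
    expect_equal(m$mIoU, o$mIoU, tolerance = 1e-12)
    expect_equal(m$acc, o$acc, tolerance = 1e-12)
    expect_equal(m$mPA, o$mPA, tolerance = 1e-12)
    # algebraic identity Dice = 2 IoU / (1 + IoU), and micro accuracy
    expect_equal(m$perClass$dice,
                 2 * m$perClass$iou / (1 + m$perClass$iou), tolerance = 1e-12)
    expect_equal(m$acc, sum(cc@tp) / 400, tolerance = 1e-12)
  }
})

test_that("metrics are equivariant under class relabelling", {
  pred <- randomMask(15L, 15L, 5L, seed = 10L)
  true <- randomMask(15L, 15L, 5L, seed = 11L)
  perm <- c(3L, 0L, 4L, 1L, 2L)           # label c -> perm[c + 1]
  m1 <- computeMetrics(confusionCounts(pred, true, 5L))
  m2 <- computeMetrics(confusionCounts(matrix(perm[pred + 1L], 15L),
                                       matrix(perm[true + 1L], 15L), 5L))
  expect_equal(sort(m1$perClass$dice), sort(m2$perClass$dice), tolerance = 1e-12)
  expect_equal(m1$mIoU, m2$mIoU, tolerance = 1e-12)
  expect_equal(m1$acc, m2$acc, tolerance = 1e-12)
})

test_that("the as-printed mean-accuracy variant equals its literal formula", {
  pred <- randomMask(10L, 10L, 3L, seed = 20L)
  true <- randomMask(10L, 10L, 3L, seed = 21L)
  cc <- confusionCounts(pred, true, 3L)
  m <- computeMetrics(cc, formula = "as-printed")
  expect_equal(m$mPA, mean(cc@tp / 100), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m$mPA, computeMetrics(cc)$mPA)))
})

test_that("percent rendering rounds half away from zero to one decimal", {
  expect_equal(formatPercent(c(0.9125, 0.99945, 0.5, 1)),
               c("91.3", "99.9", "50.0", "100.0"))
})

test_that("rank-sum p-values match enumeration and the reference implementation", {
  expect_equal(compareMethods(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  expect_equal(compareMethods(c(1, 2, 3), c(1, 2, 3)), 1)
  # rank invariance under monotone scaling
  set.seed(1)
  a <- stats::rnorm(6); b <- stats::rnorm(7, mean = 0.5)
  expect_equal(compareMethods(a, b), compareMethods(2 * a, 2 * b), tolerance = 1e-12)
  # exact path vs stats::wilcox.test for tie-free data
  for (s in 1:5) {
    set.seed(s)
    a <- stats::rnorm(5 + s %% 3); b <- stats::rnorm(7)
    expect_equal(compareMethods(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # exact path with ties vs exhaustive enumeration
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 5, 5)
  expect_equal(compareMethods(a, b), enumRankSumP(a, b), tolerance = 1e-12)
  # large samples: normal approximation with tie correction, as in the
  # reference implementation
  set.seed(9)
  a <- round(stats::rnorm(40), 1); b <- round(stats::rnorm(45, 0.3), 1)
  expect_equal(compareMethods(a, b),
               suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value),
               tolerance = 1e-9)
  expect_warning(p1 <- compareMethods(rep(2, 5), rep(2, 6)), "identical")
  expect_equal(p1, 1)
})

test_that("error maps flag exactly the disagreeing pixels", {
  a <- matrix(0L, 3L, 3L)
  expect_equal(errorMap(a, a)$map, matrix(0L, 3L, 3L))
  expect_equal(errorMap(a, a)$fraction, 0)
  b <- 1L - a
  expect_true(all(errorMap(a, b)$map == 1L))
  expect_equal(errorMap(a, b)$fraction, 1)
  c1 <- a; c1[1L, 2L] <- 1L; c1[3L, 3L] <- 2L
  em <- errorMap(c1, a)
  expect_equal(em$fraction, 2 / 9)
  expect_equal(which(em$map == 1L), c(4L, 9L))
  # fraction complements micro accuracy
  p <- randomMask(8L, 8L, 3L, seed = 5L); t <- randomMask(8L, 8L, 3L, seed = 6L)
  expect_equal(errorMap(p, t)$fraction,
               1 - computeMetrics(confusionCounts(p, t, 3L))$acc,
               tolerance = 1e-12)
  expect_error(errorMap(a, matrix(0L, 2L, 3L)), "shape")
})
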