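knee <- anatomyPreset("knee")

test_that("the sigmoid operator matches its closed form", {
  p <- knee@sigmoid
  # midpoint of the band maps to the mid weighting
  expect_equal(sigmoidScale(50, p), 0.55, tolerance = 1e-12)
  # direct evaluation at the upper band limit
  expect_equal(sigmoidScale(100, p), 0.1 + 0.9 / (1 + exp(-5)),
               tolerance = 1e-12)
  # strictly increasing across each anatomy's transition band (in double
  # precision the tails saturate far outside it)
  for (pp in list(p, anatomyPreset("hip")@sigmoid,
                  anatomyPreset("spine")@sigmoid)) {
    xs <- seq(pp@xl - 30, pp@xh + 30, by = 0.5)
    expect_true(all(diff(sigmoidScale(xs, pp)) > 0))
  }
  # open range (y_l, y_h) near the band; saturates to the limits far out
  expect_gt(sigmoidScale(p@xl - 30, p), p@yl)
  expect_lt(sigmoidScale(p@xh + 30, p), p@yh)
  expect_gte(sigmoidScale(-1e4, p), p@yl)
  expect_lte(sigmoidScale(1e4, p), p@yh)
  expect_error(sigmoidParams(100, 0, 0.1, 1))
  expect_error(sigmoidParams(0, 100, -0.1, 1))
})

test_that("scaled L1 losses reduce correctly", {
  p <- knee@sigmoid
  t2t <- matrix(c(40, 80), 1, 2)
  expect_identical(l1ScaledLoss(t2t, t2t, p), 0)
  # 2-pixel toy: only the first pixel differs
  t2p <- matrix(c(50, 80), 1, 2)
  expect_equal(l1ScaledLoss(t2t, t2p, p),
               abs(sigmoidScale(40, p) - sigmoidScale(50, p)) / 2,
               tolerance = 1e-12)
  # full-image ROI collapses the ROI variant onto the global loss
  roi <- matrix(1L, 1, 2)
  expect_equal(roiL1ScaledLoss(t2t, t2p, roi, p), l1ScaledLoss(t2t, t2p, p))
  expect_error(roiL1ScaledLoss(t2t, t2p, matrix(0L, 1, 2), p), "empty ROI")
})

test_that("SSIM loss behaves as a structural dissimilarity", {
  set.seed(1)
  a <- matrix(runif(32 * 32, 20, 120), 32, 32)
  expect_equal(ssimLoss(a, a), 0, tolerance = 1e-9)
  expect_equal(ssimLoss(a, matrix(0, 32, 32)), 1, tolerance = 0.1)
  b <- a + matrix(rnorm(32 * 32, 0, 15), 32, 32)
  expect_equal(ssimLoss(a, b), ssimLoss(b, a), tolerance = 1e-9)
  expect_gt(ssimLoss(a, b), 0)
})

test_that("feature loss is deterministic, non-negative and zero at identity", {
  ex1 <- randomFeatureExtractor(seed = 7L)
  ex2 <- randomFeatureExtractor(seed = 7L)
  set.seed(2)
  a <- matrix(runif(32 * 32, 0, 120), 32, 32)
  b <- matrix(runif(32 * 32, 0, 120), 32, 32)
  expect_identical(featureLoss(a, b, ex1), featureLoss(a, b, ex2))
  expect_identical(featureLoss(a, a, ex1), 0)
  expect_gte(featureLoss(a, b, ex1), 0)
  ex3 <- randomFeatureExtractor(seed = 8L)
  expect_false(identical(featureLoss(a, b, ex1), featureLoss(a, b, ex3)))
})

test_that("the network loss is a weighted sum with component reductions", {
  set.seed(3)
  t2t <- matrix(runif(16 * 16, 20, 90), 16, 16)
  t2p <- t2t + matrix(rnorm(16 * 16, 0, 6), 16, 16)
  roi <- matrix(0L, 16, 16); roi[5:10, 4:12] <- 1L
  ex <- randomFeatureExtractor()

  # single-component reductions
  l <- networkLoss(t2t, t2p, roi, knee, lossWeights(1, 0, 0, 0))
  expect_equal(l$total, l1ScaledLoss(t2t, t2p, knee@sigmoid))
  l <- networkLoss(t2t, t2p, roi, knee, lossWeights(0, 1, 0, 0))
  expect_equal(l$total, roiL1ScaledLoss(t2t, t2p, roi, knee@sigmoid))

  # zero at identity for any weights
  l0 <- networkLoss(t2t, t2t, roi, knee, lossWeights(1, 50, 1, 0.2), ex)
  expect_equal(l0$total, 0, tolerance = 1e-12)

  # weighted sum equals independently computed components
  w <- lossWeights(1, 100, 1.5, 0.25)
  l <- networkLoss(t2t, t2p, roi, knee, w, ex)
  dr <- 1.5 * knee@sigmoid@xh
  hand <- 1 * l1ScaledLoss(t2t, t2p, knee@sigmoid) +
    100 * roiL1ScaledLoss(t2t, t2p, roi, knee@sigmoid) +
    1.5 * ssimLoss(t2t, t2p, dynamic_range = dr) +
    0.25 * featureLoss(t2t, t2p, ex, dynamic_range = dr)
  expect_equal(l$total, hand, tolerance = 1e-12)
  expect_error(networkLoss(t2t, t2p, NULL, knee, lossWeights(1, 50, 0, 0)),
               "ROI")
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(9)
  t2t <- matrix(runif(32 * 32, 10, 90), 32, 32)
  t2p <- t2t + matrix(rnorm(32 * 32, 0, 5), 32, 32)
  roi <- matrix(0L, 32, 32); roi[10:20, 8:25] <- 1L
  ex <- randomFeatureExtractor()
  w <- lossWeights(1, 100, 1, 0.1)
  l <- networkLoss(t2t, t2p, roi, knee, w, ex, gradient = TRUE)
  eps <- 1e-4
  idx <- cbind(c(12, 15, 3, 30, 20), c(10, 20, 3, 31, 15))
  for (i in seq_len(nrow(idx))) {
    tp <- t2p; tp[idx[i, 1], idx[i, 2]] <- tp[idx[i, 1], idx[i, 2]] + eps
    lp <- networkLoss(t2t, tp, roi, knee, w, ex)$total
    tp[idx[i, 1], idx[i, 2]] <- tp[idx[i, 1], idx[i, 2]] - 2 * eps
    lm_ <- networkLoss(t2t, tp, roi, knee, w, ex)$total
    fd <- (lp - lm_) / (2 * eps)
    an <- l$grad[idx[i, 1], idx[i, 2]]
    expect_equal(an, fd, tolerance = 1e-4)
  }
})
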