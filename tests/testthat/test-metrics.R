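test_that("ROI NRMSE matches hand evaluation and is scale-equivariant", {
  roi <- c(1L, 1L, 1L)
  expect_equal(roiNrmse(c(40, 50, 60), c(40, 50, 60), roi), 0)
  # uniform 10% inflation gives exactly 0.1
  expect_equal(roiNrmse(c(40, 50, 60), 1.1 * c(40, 50, 60), roi), 0.1,
               tolerance = 1e-12)
  # 3-pixel hand evaluation
  expect_equal(roiNrmse(c(40, 50, 60), c(44, 50, 54), roi),
               sqrt(16 + 0 + 36) / sqrt(40^2 + 50^2 + 60^2),
               tolerance = 1e-12)
  # scaling both maps by c > 0 leaves the ratio unchanged
  set.seed(2)
  a <- runif(20, 20, 80); b <- a + rnorm(20)
  m <- rep(1L, 20)
  expect_equal(roiNrmse(a, b, m), roiNrmse(3.7 * a, 3.7 * b, m),
               tolerance = 1e-12)
  expect_error(roiNrmse(a, b, rep(0L, 20)), "empty")
  expect_error(roiNrmse(rep(0, 3), 1:3, roi), "zero")
})

test_that("T2-value equivalents are NRMSE times the ROI mean", {
  t2 <- c(40, 50, 60); roi <- rep(1L, 3)
  expect_equal(t2Equivalent(0, t2, roi), 0)
  expect_equal(t2Equivalent(0.1, t2, roi), 5)
  ph <- testPhantom(seed = 31L)
  pred <- ph@t2 * 1.05; pred[is.na(pred)] <- 0
  tr <- ph@t2; tr[is.na(tr)] <- 0
  nr <- roiNrmse(tr, pred, ph@roi@labels)
  expect_equal(t2Equivalent(nr, tr, ph@roi@labels),
               nr * mean(tr[ph@roi@labels > 0]))
})

test_that("Bland-Altman bias and limits of agreement are correct", {
  x <- c(40, 45, 50, 55)
  ba <- blandAltman(x, x)
  expect_equal(ba$bias, 0); expect_equal(diff(ba$loa), 0)
  ba <- blandAltman(x, x + 3)
  expect_equal(ba$bias, 3); expect_equal(ba$sd, 0)
  set.seed(4)
  y <- x + rnorm(4)
  ba <- blandAltman(x, y)
  d <- y - x
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa, mean(d) + c(-1.96, 1.96) * sd(d))
  expect_error(blandAltman(1, 2), "2 pairs")
})

test_that("ROI Pearson correlation matches the textbook formula", {
  roi <- rep(1L, 5)
  x <- c(40, 45, 50, 55, 60)
  expect_equal(pearsonRoi(x, x, roi)$r, 1)
  expect_equal(pearsonRoi(x, 2 * x + 3, roi)$r, 1)
  set.seed(5)
  y <- x + rnorm(5, 0, 4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- pearsonRoi(x, y, roi)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_error(pearsonRoi(x, rep(1, 5), roi), "variance")
  expect_error(pearsonRoi(x[1:2], y[1:2], roi[1:2]), "3 ROI")
})

test_that("GLCM metrics of a constant ROI are degenerate as expected", {
  m <- matrix(42, 6, 6)
  g <- glcmMetrics(m, matrix(1L, 6, 6))
  expect_equal(unname(g), c(0, 0, 1, 1, 1))
})

test_that("GLCM metrics equal the brute-force pair-enumeration oracle", {
  set.seed(6)
  for (rep in 1:4) {
    m <- matrix(runif(64, 0, 150), 8, 8)
    roi <- matrix(sample(c(0L, 1L), 64, replace = TRUE, prob = c(.3, .7)),
                  8, 8)
    g <- glcmMetrics(m, roi, n_levels = 8L, t2_range = c(0, 150))
    ref <- refGlcm(m, roi, 8L, c(0, 150))
    expect_equal(g, ref, tolerance = 1e-12)
  }
  # 2x2 two-level checkerboard with full ROI, hand-checkable
  cb <- matrix(c(10, 140, 140, 10), 2, 2)
  g <- glcmMetrics(cb, matrix(1L, 2, 2), n_levels = 2L, t2_range = c(0, 150))
  expect_equal(g, refGlcm(cb, matrix(1L, 2, 2), 2L, c(0, 150)),
               tolerance = 1e-12)
  # horizontal and vertical offsets see only (1,2)/(2,1) pairs; diagonals
  # see only identical pairs
  expect_equal(unname(g["contrast"]), mean(c(1, 0, 1, 0)))
  expect_equal(unname(g["energy"]), unname(sqrt(g["asm"])))
})

test_that("GLCM metrics are invariant under transposition", {
  set.seed(7)
  m <- matrix(runif(49, 0, 150), 7, 7)
  roi <- matrix(1L, 7, 7)
  expect_equal(glcmMetrics(m, roi), glcmMetrics(t(m), roi),
               tolerance = 1e-12)
})

test_that("pooling co-occurrence counts across slices matches manual pooling", {
  set.seed(8)
  m <- array(runif(2 * 25, 0, 150), c(5, 5, 2))
  roi <- array(1L, c(5, 5, 2))
  expect_equal(glcmMetrics(m, roi, 8L), refGlcm(m, roi, 8L, c(0, 150)),
               tolerance = 1e-12)
})

test_that("consistency ICC matches a long-hand two-way ANOVA", {
  x <- c(0.91, 0.85, 0.78, 0.95, 0.66)
  y <- c(0.89, 0.80, 0.81, 0.90, 0.70)
  out <- iccSingleRater(x, y)
  # mean squares from a two-way ANOVA, computed with aov()
  dat <- data.frame(val = c(x, y),
                    scan = factor(rep(1:5, 2)),
                    rater = factor(rep(1:2, each = 5)))
  ms <- summary(aov(val ~ scan + rater, dat))[[1]]$`Mean Sq`
  msr <- ms[1]; mse <- ms[3]
  expect_equal(out$icc, (msr - mse) / (msr + mse), tolerance = 1e-12)
  expect_lt(out$ci[1], out$icc); expect_gt(out$ci[2], out$icc)
  expect_equal(out$p, pf(msr / mse, 4, 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ICC is 1 for identical and constant-shifted measurements", {
  x <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(iccSingleRater(x, x)$icc, 1)
  expect_equal(iccSingleRater(x, x + 0.1)$icc, 1)
  # absolute agreement penalises the shift
  expect_lt(iccSingleRater(x, x + 0.1, type = "agreement")$icc, 1)
  expect_error(iccSingleRater(rep(1, 4), rep(1, 4)), "variance")
  expect_error(iccSingleRater(x[1:2], x[1:2]), "3 scans")
})

test_that("metric reports cover every compartment", {
  ph <- testPhantom(seed = 35L)
  tr <- ph@t2; tr[is.na(tr)] <- 0
  pred <- tr * 1.08
  rep_ <- metricReport(tr, pred, ph@roi@labels)
  expect_setequal(rep_$compartment,
                  setdiff(unique(as.vector(ph@roi@labels)), 0L))
  expect_true(all(abs(rep_$nrmse - 0.08) < 1e-10))
  # compartments without internal T2 variation yield NA correlations
  expect_true(all(is.na(rep_$pearson_r) | rep_$pearson_r > 0.999))
})
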