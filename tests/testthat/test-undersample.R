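test_that("elliptical support hits the requested area fraction", {
  s <- ellipticalSupport(128, 22, 0.7)
  frac <- sum(s) / (128 * 22)
  expect_gte(frac, 0.69); expect_lte(frac, 0.71)
  # corners are never acquired
  expect_false(s[1, 1] || s[1, 22] || s[128, 1] || s[128, 22])
  # fraction 1 selects the full rectangle
  expect_true(all(ellipticalSupport(16, 16, 1.0)))
})

test_that("masks are reproducible and unique per echo", {
  plan <- samplingPlan(4, c(64L, 16L), seed = 11L)
  m1 <- poissonMask(plan, 1L)
  m1b <- poissonMask(plan, 1L)
  m2 <- poissonMask(plan, 2L)
  expect_identical(m1, m1b)
  expect_false(identical(as.vector(m1), as.vector(m2)))
})

test_that("the central region is fully sampled in every echo mask", {
  plan <- samplingPlan(6, c(64L, 16L), seed = 3L)
  sm <- buildSamplingMask(plan)
  central <- AccelT2:::centralRegion(64L, 16L, 0.05) & sm@support
  for (e in seq_len(plan@nEchoes))
    expect_true(all(sm@masks[, , e][central]))
  validObject(sm)
})

test_that("R = 1 samples every ellipse-interior point", {
  plan <- samplingPlan(1, c(32L, 16L), seed = 1L)
  m <- poissonMask(plan, 1L)
  s <- ellipticalSupport(32, 16, 0.7)
  expect_identical(unname(m[s]), rep(TRUE, sum(s)))
  expect_equal(attr(m, "realizedR"), 1)
})

test_that("sampling density is center-weighted", {
  plan <- samplingPlan(4, c(128L, 22L), seed = 5L)
  m <- poissonMask(plan, 1L)
  s <- ellipticalSupport(128, 22, 0.7)
  rel <- sqrt(0.7 / (pi / 4))
  d <- AccelT2:::ellipseCoords(128L, 22L, rel, rel)
  d <- d / max(d[s])
  frac <- function(lo, hi) {
    sel <- s & d > lo & d <= hi
    sum(m[sel]) / sum(sel)
  }
  f1 <- frac(0, 1 / 3); f2 <- frac(1 / 3, 2 / 3); f3 <- frac(2 / 3, 1)
  expect_gte(f1, f2)
  expect_gte(f2, f3)
})

test_that("echo line sharing copies the temporally closest sampled donor", {
  te <- c(0, 12.9, 25.7, 51.4)
  d <- c(4L, 4L)
  ks <- lapply(1:4, function(e) matrix(complex(real = e, imaginary = e), d[1], d[2]))
  masks <- array(FALSE, c(d, 4L))

  # a line sampled at all echoes keeps its own data everywhere
  masks[1, 1, ] <- TRUE
  # a line sampled only at TE = 0 donates to all later echoes
  masks[2, 2, 1] <- TRUE
  # equidistant donors: echoes 1 (0 ms) and 3 (25.7 ms) for echo 2 (12.9)
  # are 12.9 and 12.8 ms away -- echo 3 is closer; craft a true tie instead
  filled <- shareEchoLines(ks, masks, te)
  for (e in 1:4) expect_equal(filled[[e]][1, 1], ks[[e]][1, 1])
  for (e in 2:4) expect_equal(filled[[e]][2, 2], ks[[1]][2, 2])
  # unsampled everywhere -> zero at all echoes
  for (e in 1:4) expect_equal(filled[[e]][3, 3], 0 + 0i)

  # exact tie: symmetric echo times, donors 0 and 20 ms for the 10 ms echo;
  # the earlier echo must win
  te2 <- c(0, 10, 20)
  ks2 <- lapply(1:3, function(e) matrix(complex(real = e), 2, 2))
  masks2 <- array(FALSE, c(2L, 2L, 3L))
  masks2[1, 1, c(1, 3)] <- TRUE
  f2 <- shareEchoLines(ks2, masks2, te2)
  expect_equal(f2[[2]][1, 1], ks2[[1]][1, 1])
})

test_that("sharing never invents data", {
  ph <- testPhantom(seed = 21L)
  plan <- samplingPlan(4, c(32L, 8L), seed = 13L)
  sm <- buildSamplingMask(plan)
  te <- echoTimes(ph@echoes)
  K <- lapply(1:4, function(e)
    AccelT2:::fftshift2(fft(ph@echoes@data[, 1, , e])))
  filled <- shareEchoLines(K, sm@masks, te)
  for (e in 1:4) {
    nz <- which(filled[[e]] != 0)
    for (idx in nz) {
      matches <- vapply(1:4, function(d) isTRUE(
        all.equal(filled[[e]][idx], K[[d]][idx])), logical(1))
      expect_true(any(matches))
    }
  }
})

test_that("R = 1 with full rectangular coverage is an identity transform", {
  ph <- testPhantom(seed = 2L)
  plan <- samplingPlan(1, c(32L, 8L), ellipse_area_fraction = 1.0,
                       central_square_area_fraction = 0.05, seed = 1L)
  und <- undersampleVolume(ph@echoes, plan)
  expect_equal(und$echoes@data, ph@echoes@data, tolerance = 1e-10)
})

test_that("aliased volumes keep dimensions and mismatched grids error", {
  ph <- testPhantom(seed = 3L)
  und <- undersampleVolume(ph@echoes, samplingPlan(4, c(32L, 8L), seed = 2L))
  expect_identical(dim(und$echoes@data), dim(ph@echoes@data))
  expect_error(undersampleVolume(ph@echoes, samplingPlan(4, c(16L, 8L))),
               "grid")
})
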