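test_that("phantom generation is bit-reproducible from its seed", {
  cfg <- phantomConfig(seed = 42L)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(a@t2, b@t2)
  expect_identical(a@pd, b@pd)
  expect_identical(a@roi@labels, b@roi@labels)
  expect_identical(a@echoes@data, b@echoes@data)
})

test_that("without noise or lesions every ROI voxel carries its class T2", {
  ph <- generatePhantom(phantomConfig(noise_sigma = 0, lesion_count = 0L,
                                      seed = 5L))
  for (lab in setdiff(unique(as.vector(ph@roi@labels)), 0L)) {
    vals <- unique(ph@t2[ph@roi@labels == lab])
    expect_length(vals, 1L)
    expect_gte(vals, 30); expect_lte(vals, 60)
  }
})

test_that("ROI geometry varies across seeds while class values stay in range", {
  a <- generatePhantom(phantomConfig(seed = 1L))
  b <- generatePhantom(phantomConfig(seed = 2L))
  expect_false(identical(a@roi@labels, b@roi@labels))
  for (ph in list(a, b)) {
    sel <- ph@roi@labels > 0
    # lesions may raise T2 above the class range by the configured delta
    expect_gte(min(ph@t2[sel]), 30)
    expect_lte(max(ph@t2[sel]), 60 + ph@config$lesion_t2_delta)
  }
})

test_that("spine preset places elliptical disc compartments at higher T2", {
  ph <- generatePhantom(phantomConfig(anatomy = "spine", lesion_count = 0L,
                                      noise_sigma = 0, seed = 3L))
  labs <- setdiff(unique(as.vector(ph@roi@labels)), 0L)
  expect_gte(length(labs), 2L)
  expect_gte(min(ph@t2[ph@roi@labels > 0]), 60)
  expect_lte(max(ph@t2[ph@roi@labels > 0]), 130)
})

test_that("a grid too small for the ROI raises an explicit error", {
  expect_error(generatePhantom(phantomConfig(grid = c(8L, 8L, 4L))),
               "too small")
})

test_that("noiseless echoes follow the mono-exponential model exactly", {
  ph <- generatePhantom(phantomConfig(noise_sigma = 0, seed = 7L))
  te <- echoTimes(ph)
  # TE = 0 image equals proton density
  expect_equal(ph@echoes@data[, , , 1], ph@pd, tolerance = 1e-12)
  # log-signal is linear in TE with slope -1/T2 (perfect fit per voxel)
  tissue <- which(ph@pd > 0)
  sig <- sapply(seq_along(te), function(e) ph@echoes@data[, , , e][tissue])
  for (k in c(1L, 50L, length(tissue))) {
    fit <- lm(log(sig[k, ]) ~ te)
    r2 <- suppressWarnings(summary(fit)$r.squared)  # "perfect fit" warning
    expect_equal(unname(r2), 1, tolerance = 1e-10)
    expect_equal(unname(-1 / coef(fit)[2]), ph@t2[tissue[k]],
                 tolerance = 1e-8)
  }
})

test_that("closed-form signal value is reproduced", {
  t2 <- array(40, c(2, 2, 1)); pd <- array(500, c(2, 2, 1))
  es <- simulateEchoes(t2, pd, c(0, 12.9, 25.7, 51.4), noise_sigma = 0)
  expect_equal(es@data[1, 1, 1, 4], 500 * exp(-51.4 / 40), tolerance = 1e-12)
})

test_that("Rician noise has the right background mean and support", {
  t2 <- array(40, c(120, 120, 1)); pd <- array(0, c(120, 120, 1))
  pd[1, 1, 1] <- 500                       # peak PD sets the noise scale
  sigma <- 0.02 * 500
  es <- simulateEchoes(t2, pd, c(0, 12.9), noise_sigma = 0.02, seed = 9L)
  expect_true(all(es@data >= 0))
  bg <- es@data[, , , 1][pd == 0]
  expect_gt(length(bg), 1e4)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(phantomConfig(noise_sigma = -0.1), "noise_sigma")
  expect_error(phantomConfig(echo_times = c(5, 10, 20)), "start at 0|echo_times")
  expect_error(phantomConfig(echo_times = c(0, 20, 10)), "echo_times")
  expect_error(simulateEchoes(array(1, c(2, 2, 1)), array(1, c(3, 2, 1)),
                              c(0, 10)), "dimensions")
})
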