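test_that("the three variants reproduce the published parameter counts", {
  expect_identical(nParameters(modelConfig("full")), 39808710)
  expect_identical(nParameters(modelConfig("no_rnn")), 35116037)
  expect_identical(nParameters(modelConfig("reduced")), 9958246)
  # the reduced variant halves every depth except inputs and map outputs
  full <- modelConfig("full"); red <- modelConfig("reduced")
  expect_identical(red@streamDepths, full@streamDepths %/% 2L)
  expect_identical(red@encoderDepths, full@encoderDepths %/% 2L)
})

test_that("compiled convolution kernels match a direct-loop reference", {
  set.seed(3)
  x <- array(rnorm(10 * 8 * 3), c(10, 8, 3))
  w <- array(rnorm(3 * 3 * 3 * 5), c(3, 3, 3, 5)); b <- rnorm(5)
  for (st in c(1L, 2L)) {
    expect_equal(AccelT2:::.cppConvFwd(x, w, b, st, 1L),
                 refConvFwd(x, w, b, st, 1), tolerance = 1e-5)
  }
  wt <- array(rnorm(4 * 4 * 6 * 3), c(4, 4, 6, 3)); bt <- rnorm(6)
  expect_equal(AccelT2:::.cppTConvFwd(x, wt, bt, 2L, 1L),
               refTConvFwd(x, wt, bt, 2, 1), tolerance = 1e-5)
})

test_that("forward pass matches a double-precision replica of the topology", {
  m <- buildModel(tinyModelConfig(), seed = 2L)
  set.seed(1)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(AccelT2:::netForward(m, x), refNetForward(m, x),
               tolerance = 1e-5)
  m2 <- buildModel(tinyModelConfig("no_rnn"), seed = 2L)
  expect_equal(AccelT2:::netForward(m2, x), refNetForward(m2, x),
               tolerance = 1e-5)
})

test_that("backpropagation matches finite differences of the double replica", {
  m <- buildModel(tinyModelConfig(), seed = 2L)
  set.seed(1)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  tgt <- matrix(runif(64, 0, 1), 8, 8)
  tp <- AccelT2:::netForward(m, x, tape = TRUE)
  dy <- 2 * (tp$y - tgt) / length(tgt)
  G <- AccelT2:::netBackward(m, x, tp, dy)
  lossRef <- function(model) mean((refNetForward(model, x) - tgt)^2)
  eps <- 1e-6
  set.seed(4)
  # one layer of every kind; every layer's wiring is already covered by
  # the double-precision forward comparison above
  pick <- c("stream_w1", "stream_b2", "inter_w1", "gain2", "enc_w1",
            "enc_b2", "dec_t_w1", "dec_c_w2", "dec_t_b2", "head_w",
            "head_b")
  for (nm in pick) {
    p <- m@params[[nm]]
    js <- unique(c(1L, sample.int(length(p), min(2L, length(p)))))
    for (j in js) {
      m2 <- m; m2@params[[nm]][j] <- p[j] + eps
      lp <- lossRef(m2)
      m2@params[[nm]][j] <- p[j] - eps
      lm_ <- lossRef(m2)
      fd <- (lp - lm_) / (2 * eps)
      expect_lt(abs(G[[nm]][j] - fd),
                1e-3 * max(abs(fd), abs(G[[nm]][j]), 1e-3))
    }
  }
})

test_that("prediction obeys the shape contract and rejects bad shapes", {
  m <- buildModel(tinyModelConfig("no_rnn", n_echoes = 4L), seed = 1L)
  # tiny config has 2 stride-2 levels, but the exported contract is the
  # default 5-level UNet; exercise it on the reduced variant
  red <- buildModel(modelConfig("reduced"), seed = 1L)
  x <- array(runif(64 * 32 * 4) * 500, c(64, 32, 4))
  y <- predictMap(red, x)
  expect_identical(dim(y), c(64L, 32L))
  expect_true(all(is.finite(y)))
  # inference determinism
  expect_identical(y, predictMap(red, x))
  # zero input stays finite
  expect_true(all(is.finite(predictMap(red, array(0, c(32, 32, 4))))))
  expect_error(predictMap(red, array(0, c(30, 32, 4))), "divisible")
  expect_error(predictMap(red, array(0, c(32, 32, 3))), "echo")
})

test_that("lambda_w = 0 decouples the echo streams", {
  cfg <- modelConfig("reduced", lambda_w = 0)
  m <- buildModel(cfg, seed = 5L)
  set.seed(6)
  x <- array(runif(32 * 32 * 4) * 500, c(32, 32, 4))
  x2 <- x
  x2[, , 2] <- x[, , 2][rev(seq_len(32)), ]    # permute the second echo
  t1 <- AccelT2:::netForward(m, x, tape = TRUE)
  t2 <- AccelT2:::netForward(m, x2, tape = TRUE)
  # other streams' pre-concatenation outputs are unchanged
  for (e in c(1L, 3L, 4L))
    expect_identical(t1$unet_in[, , e], t2$unet_in[, , e])
  expect_false(identical(t1$unet_in[, , 2], t2$unet_in[, , 2]))

  # with lambda_w > 0 the perturbation propagates to later echoes
  m2 <- buildModel(modelConfig("reduced"), seed = 5L)
  s1 <- AccelT2:::netForward(m2, x, tape = TRUE)
  s2 <- AccelT2:::netForward(m2, x2, tape = TRUE)
  expect_identical(s1$unet_in[, , 1], s2$unet_in[, , 1])
  expect_false(identical(s1$unet_in[, , 3], s2$unet_in[, , 3]))
})

test_that("model display reports variant and parameter count", {
  m <- buildModel(modelConfig("reduced"), materialise = FALSE)
  expect_output(show(m), "reduced")
  expect_output(show(m), "9,958,246")
})
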