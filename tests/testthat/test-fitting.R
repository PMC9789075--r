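test_that("noiseless mono-exponential signals are recovered exactly", {
  ph <- generatePhantom(phantomConfig(noise_sigma = 0, seed = 4L))
  fit <- fitT2(ph@echoes)
  sel <- ph@pd > 0
  expect_lt(max(abs(fit@t2[sel] - ph@t2[sel]) / ph@t2[sel]), 1e-6)
  expect_lt(max(abs(fit@amplitude[sel] - ph@pd[sel]) / ph@pd[sel]), 1e-6)
  expect_true(all(fit@valid[sel]))
  expect_false(any(fit@valid[!sel]))
  expect_true(all(is.na(fit@t2[!sel])))
})

test_that("the fit is invariant to uniform positive signal scaling", {
  ph <- testPhantom(seed = 8L)
  f1 <- fitT2(ph@echoes)
  scaled <- new("EchoSeries", data = ph@echoes@data * 7.3,
                echoTimes = echoTimes(ph@echoes))
  f2 <- fitT2(scaled)
  sel <- f1@valid & !f1@atBound
  expect_equal(f1@t2[sel], f2@t2[sel], tolerance = 1e-8)
  expect_equal(f2@amplitude[sel] / f1@amplitude[sel],
               rep(7.3, sum(sel)), tolerance = 1e-8)
})

test_that("constant (non-decaying) signal clamps to the upper bound and is flagged", {
  dat <- array(100, c(2, 2, 1, 4))
  es <- new("EchoSeries", data = dat, echoTimes = c(0, 12.9, 25.7, 51.4))
  fit <- fitT2(es)
  expect_true(all(fit@atBound))
  expect_equal(unname(fit@t2[1, 1, 1]), 300)
})

test_that("Monte-Carlo median bias is below 2% at 1% Rician noise", {
  n <- 100L
  t2 <- array(40, c(n, n, 1)); pd <- array(500, c(n, n, 1))
  es <- simulateEchoes(t2, pd, c(0, 12.9, 25.7, 51.4), noise_sigma = 0.01,
                       seed = 33L)
  fit <- fitT2(es)
  expect_gte(sum(fit@valid), 1e4)
  expect_lt(abs(median(fit@t2[fit@valid]) - 40) / 40, 0.02)
})

test_that("vectorised LM agrees with a general-purpose LM optimiser", {
  skip_if_not_installed("minpack.lm")
  te <- c(0, 12.9, 25.7, 51.4)
  set.seed(17)
  for (k in 1:5) {
    a0 <- runif(1, 300, 600); t20 <- runif(1, 20, 90)
    sig <- a0 * exp(-te / t20) + rnorm(4, sd = 3)
    sig <- pmax(sig, 1)
    dat <- array(rep(sig, each = 1), c(1, 1, 1, 4))
    fit <- fitT2(new("EchoSeries", data = dat, echoTimes = te))
    ref <- minpack.lm::nlsLM(y ~ A * exp(-te / T2),
                             data = data.frame(y = sig, te = te),
                             start = list(A = a0, T2 = t20))
    expect_equal(unname(fit@t2[1, 1, 1]), unname(coef(ref)["T2"]),
                 tolerance = 1e-4)
  }
})

test_that("LM refinement never worsens the log-linear initialisation", {
  te <- c(0, 12.9, 25.7, 51.4)
  set.seed(23)
  n <- 50L
  A <- runif(n, 200, 600); T2 <- runif(n, 15, 120)
  sig <- sapply(te, function(t) pmax(A * exp(-t / T2) + rnorm(n, sd = 5), 0.5))
  dat <- array(sig, c(n, 1, 1, 4))
  fit <- fitT2(new("EchoSeries", data = dat, echoTimes = te))
  # log-linear initialisation recomputed independently
  for (i in seq_len(n)) {
    y <- log(pmax(sig[i, ], .Machine$double.eps))
    co <- coef(lm(y ~ te))
    t2i <- min(max(ifelse(co[2] < 0, -1 / co[2], 300), 1), 300)
    ai <- exp(co[1])
    rss0 <- sum((sig[i, ] - ai * exp(-te / t2i))^2)
    rss1 <- sum((sig[i, ] - fit@amplitude[i, 1, 1] *
                   exp(-te / fit@t2[i, 1, 1]))^2)
    expect_lte(rss1, rss0 + 1e-9)
  }
})

test_that("fewer than 3 echoes is rejected", {
  dat <- array(1, c(2, 2, 1, 2))
  es <- new("EchoSeries", data = dat, echoTimes = c(0, 12.9))
  expect_error(fitT2(es), "3 echoes")
})
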