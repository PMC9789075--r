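test_that("per-slice signal scaling hits the target percentile range", {
  ph <- testPhantom(seed = 12L)
  for (anat in c("knee", "hip")) {
    target <- if (anat == "hip") 100 else 500
    scaled <- scaleSignals(ph@echoes, anat)
    for (z in c(1L, 4L)) {
      v <- scaled@data[, , z, ]
      q <- quantile(v, c(0.025, 0.975), names = FALSE)
      expect_lt(abs(q[1]), 0.5)
      expect_lt(abs(q[2] - target), 0.5)
    }
  }
  # constant slices pass through with a warning (one per slice)
  const <- new("EchoSeries", data = array(5, c(8, 8, 2, 2)),
               echoTimes = c(0, 10))
  ws <- capture_warnings(out <- scaleSignals(const, "knee"))
  expect_true(length(ws) >= 1 && all(grepl("constant", ws)))
  expect_equal(out@data, const@data)
})

test_that("pure multiplicative scaling leaves fitted T2 unchanged", {
  # signal scaling rescales intensities; T2 is a decay-rate property and
  # must be unaffected by a uniform gain
  ph <- generatePhantom(phantomConfig(noise_sigma = 0, seed = 14L))
  gained <- new("EchoSeries", data = ph@echoes@data * 0.37,
                echoTimes = echoTimes(ph@echoes))
  f1 <- fitT2(ph@echoes); f2 <- fitT2(gained)
  sel <- f1@valid
  expect_equal(f1@t2[sel], f2@t2[sel], tolerance = 1e-8)
})

test_that("augmentation applies one rigid transform to images, map and mask", {
  ph <- testPhantom(seed = 15L)
  plan <- samplingPlan(2, c(32L, 8L), seed = 3L)
  ts <- buildTrainingSet(list(ph), plan, "knee")
  s <- ts[[1]]
  set.seed(99)
  aug <- AccelT2:::augmentSample(s, max_tr = 4, max_rot = 5)
  # recover the drawn transform and check every channel used the same one
  set.seed(99)
  dy <- sample.int(9, 1) - 5; dx <- sample.int(9, 1) - 5
  ang <- runif(1, -5, 5)
  for (e in 1:4)
    expect_equal(aug$x[, , e],
                 AccelT2:::warpImage(s$x[, , e], dy, dx, ang, "bilinear"))
  expect_equal(aug$y, AccelT2:::warpImage(s$y, dy, dx, ang, "bilinear"))
  expect_equal(aug$roi, AccelT2:::warpImage(s$roi, dy, dx, ang, "nearest"))
  # the label mask stays integer-valued under nearest-neighbour warping
  expect_true(all(aug$roi %in% unique(as.vector(s$roi))))
})

test_that("training is seeded, improves the loss and returns the best checkpoint", {
  ph1 <- testPhantom(seed = 16L); ph2 <- testPhantom(seed = 17L)
  plan <- samplingPlan(4, c(32L, 8L), seed = 5L)
  ts <- buildTrainingSet(list(ph1), plan, "knee")[1:2]
  vs <- buildTrainingSet(list(ph2), plan, "knee")[1]
  cfg <- tinyModelConfig("full", n_echoes = 4L)
  # 32x32 inputs need 5 halvings in the default UNet but only 2 here
  model <- buildModel(cfg, seed = 3L)
  # enough epochs for the tiny run to clear the warmup ramp
  tc <- trainConfig(max_epochs = 15L, patience = 15L, aug_translate = 2,
                    aug_rotate = 3, seed = 21L)
  w <- lossWeights(1, 100, 0, 0)
  fit1 <- trainModel(model, ts, vs, tc, anatomyPreset("knee"), w)
  fit2 <- trainModel(model, ts, vs, tc, anatomyPreset("knee"), w)
  # determinism: identical loss curves for identical seeds
  expect_identical(fit1$history, fit2$history)
  # optimisation sanity on the training loss
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  # the returned checkpoint is the validation minimum, not the last epoch
  expect_identical(fit1$best_epoch, which.min(fit1$history$val_loss))
  m_at_best <- fit1$model
  vl <- AccelT2:::sampleLoss(m_at_best, vs[[1]], anatomyPreset("knee"), w,
                             NULL)$loss
  expect_equal(vl, min(fit1$history$val_loss), tolerance = 1e-9)
  expect_error(trainModel(model, list(), vs, tc), "empty")
})

test_that("hyperparameter search respects the printed ranges and is seeded", {
  ph1 <- testPhantom(seed = 18L); ph2 <- testPhantom(seed = 19L)
  plan <- samplingPlan(4, c(32L, 8L), seed = 7L)
  ts <- buildTrainingSet(list(ph1), plan, "knee")[1:2]
  vs <- buildTrainingSet(list(ph2), plan, "knee")[1]
  cfg <- tinyModelConfig("no_rnn", n_echoes = 4L)
  out <- hyperparameterSearch(ts, vs, anatomyPreset("knee"), cfg,
                              iterations = 3L, epochs_per_iteration = 1L,
                              seed = 2L)
  res <- out$results
  expect_true(all(res$l1 == 1))
  expect_true(all(res$l1_roi >= 50 & res$l1_roi <= 150))
  expect_true(all(res$ssim >= 0 & res$ssim <= 2))
  expect_true(all(res$feature >= 0 & res$feature <= 0.5))
  # single-iteration search returns the only sampled configuration
  out1 <- hyperparameterSearch(ts, vs, anatomyPreset("knee"), cfg,
                               iterations = 1L, epochs_per_iteration = 1L,
                               seed = 2L)
  expect_equal(out1$best@l1Roi, out1$results$l1_roi[1])
  # rerun with the same seed selects the same winner
  out2 <- hyperparameterSearch(ts, vs, anatomyPreset("knee"), cfg,
                               iterations = 3L, epochs_per_iteration = 1L,
                               seed = 2L)
  expect_equal(out$best, out2$best)
})
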