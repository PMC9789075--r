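#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size training batch size (slices per optimiser step).
#' @param max_epochs upper bound on epochs.
#' @param patience early-stopping patience: training stops once the
#'   validation loss has not improved for this many epochs, and the
#'   checkpoint with the minimum validation loss is returned.
#' @param aug_translate max absolute in-plane translation (pixels).
#' @param aug_rotate max absolute rotation about the slice axis (degrees).
#' @param grad_clip global gradient-norm ceiling; batch-1 training on
#'   saturating losses occasionally produces spiking, highly coherent
#'   gradients, and clipping keeps single steps from derailing the run.
#'   Set to Inf to disable.
#' @param lr_schedule "cosine" anneals the rate from the configured value
#'   to 5 percent of it across the epoch budget (after a short linear
#'   warmup), letting weakly-weighted loss components converge instead of
#'   oscillating; "constant" keeps the configured rate throughout.
#' @param seed RNG seed for initialisation, shuffling and augmentation.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learning_rate = 0.001, batch_size = 1L,
                        max_epochs = 100L, patience = 10L,
                        aug_translate = 10, aug_rotate = 5, grad_clip = 5,
                        lr_schedule = c("cosine", "constant"), seed = 1L) {
  new("TrainConfig", learningRate = learning_rate,
      batchSize = as.integer(batch_size), maxEpochs = as.integer(max_epochs),
      patience = as.integer(patience), augTranslate = aug_translate,
      augRotate = aug_rotate, gradClip = grad_clip,
      lrSchedule = match.arg(lr_schedule), seed = as.integer(seed))
}

#' Per-slice signal scaling
#'
#' Linearly rescales each slice of a multi-echo series so that the middle
#' 95\% of its pixel values fall between 0 and the anatomy's target (500
#' for knee and spine, 100 for hip): the 2.5th percentile maps to 0 and
#' the 97.5th to the target. Percentiles are computed jointly over the
#' slice's echo images so the relative T2 decay is preserved; the fitted
#' T2 of a scaled series therefore differs from the original only through
#' the additive offset, and the scaling is recorded in the returned
#' attributes.
#'
#' @param echo_series an \linkS4class{EchoSeries}.
#' @param anatomy anatomy name or an \linkS4class{AnatomyPreset}.
#' @return a scaled \linkS4class{EchoSeries} with attribute "scaling"
#'   (per-slice a, b of a * x + b).
#' @export
scaleSignals <- function(echo_series, anatomy = "knee") {
  stopifnot(is(echo_series, "EchoSeries"))
  preset <- if (is(anatomy, "AnatomyPreset")) anatomy else anatomyPreset(anatomy)
  target <- preset@signalTarget
  d <- dim(echo_series@data)
  out <- echo_series@data
  sc <- matrix(0, d[3], 2, dimnames = list(NULL, c("a", "b")))
  for (z in seq_len(d[3])) {
    v <- echo_series@data[, , z, ]
    q <- quantile(v, c(0.025, 0.975), names = FALSE)
    if (q[2] - q[1] < .Machine$double.eps) {
      warning(sprintf("slice %d is constant; passing through unscaled", z))
      sc[z, ] <- c(1, 0)
      next
    }
    a <- target / (q[2] - q[1]); b <- -a * q[1]
    out[, , z, ] <- a * v + b
    sc[z, ] <- c(a, b)
  }
  out[out < 0] <- 0
  res <- new("EchoSeries", data = out, echoTimes = echo_series@echoTimes)
  attr(res, "scaling") <- sc
  res
}

## One training sample: x (H, W, E) scaled aliased echoes, y (H, W) target
## T2 map, roi (H, W) labels. Targets are the maps fitted from the fully
## sampled series -- the reference a real pipeline trains against -- with
## the exact simulation truth as fallback.
sliceSamples <- function(phantom, aliased, slices = NULL, target = NULL) {
  d <- dim(aliased@data)
  if (is.null(slices)) slices <- seq_len(d[3])
  if (is.null(target)) target <- phantom@t2
  lapply(slices, function(z) {
    x <- aliased@data[, , z, , drop = FALSE]
    dim(x) <- c(d[1], d[2], d[4])
    y <- target[, , z]
    y[is.na(y)] <- 0
    list(x = x, y = y, roi = phantom@roi@labels[, , z])
  })
}

#' Assemble a training set from phantoms
#'
#' Undersamples each phantom's echo series at the plan, scales signals per
#' slice, and extracts per-slice training samples (aliased echoes, truth
#' T2 map, ROI mask). Only slices intersecting the ROI are kept by
#' default, mirroring the use of segmented slices for ROI-specific
#' training.
#'
#' @param phantoms list of \linkS4class{PhantomTruth} objects.
#' @param plan a \linkS4class{SamplingPlan}; its seed is offset per
#'   phantom so each sees a different realisation.
#' @param anatomy anatomy name or preset for signal scaling.
#' @param roi_slices_only keep only slices containing ROI pixels.
#' @param fit_targets use the T2 map fitted from the fully sampled series
#'   as the training target (the reference real pipelines train against);
#'   if FALSE, the exact simulation truth is used.
#' @return list of samples.
#' @export
buildTrainingSet <- function(phantoms, plan, anatomy = "knee",
                             roi_slices_only = TRUE, fit_targets = TRUE) {
  out <- list()
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    target <- if (fit_targets) {
      tm <- fitT2(ph@echoes)@t2
      tm[is.na(tm)] <- 0
      tm
    } else NULL
    plan_i <- samplingPlan(plan@R, plan@grid, plan@nEchoes,
                           plan@ellipseAreaFraction,
                           plan@centralSquareAreaFraction,
                           seed = deriveSeed(plan@seed, i),
                           calibration_tolerance = plan@calibrationTolerance,
                           alpha = plan@alpha)
    und <- undersampleVolume(ph@echoes, plan_i)
    scaled <- scaleSignals(und$echoes, anatomy)
    keep <- if (roi_slices_only) {
      which(apply(ph@roi@labels > 0, 3, any))
    } else seq_len(dim(ph@t2)[3])
    out <- c(out, sliceSamples(ph, scaled, keep, target))
  }
  out
}

## Apply one random rigid augmentation to a sample: identical transform for
## every echo image, the target map and the ROI mask. Images and the
## target map resample bilinearly (consistent sub-pixel alignment with the
## inputs); the label mask uses nearest neighbour.
augmentSample <- function(s, max_tr, max_rot) {
  dy <- if (max_tr > 0) sample.int(2 * max_tr + 1, 1) - max_tr - 1 else 0
  dx <- if (max_tr > 0) sample.int(2 * max_tr + 1, 1) - max_tr - 1 else 0
  ang <- if (max_rot > 0) runif(1, -max_rot, max_rot) else 0
  if (dy == 0 && dx == 0 && ang == 0) return(s)
  x <- s$x
  for (e in seq_len(dim(x)[3]))
    x[, , e] <- warpImage(s$x[, , e], dy, dx, ang, "bilinear")
  list(x = x, y = warpImage(s$y, dy, dx, ang, "bilinear"),
       roi = warpImage(s$roi, dy, dx, ang, "nearest"))
}

deepCopyParams <- function(params) lapply(params, function(p) p + 0)

sampleLoss <- function(model, s, preset, weights, extractor,
                       gradient = FALSE) {
  tp <- netForward(model, s$x, tape = gradient)
  y <- if (gradient) tp$y else tp
  l <- networkLoss(s$y, y, roi = s$roi, preset = preset, weights = weights,
                   extractor = extractor, gradient = gradient)
  if (!gradient) return(list(loss = l$total, components = l$components))
  G <- netBackward(model, s$x, tp, l$grad)
  list(loss = l$total, components = l$components, grads = G)
}

#' Train a T2-prediction network
#'
#' Optimises the network on per-slice samples with Adam at the configured
#' learning rate and batch size, applying a fresh random rigid
#' augmentation (identical across the echo images, target map and ROI
#' mask of a sample) at every step. After each epoch the un-augmented
#' validation loss is evaluated; training stops when it has not improved
#' for \code{patience} epochs, and the parameters with the best
#' validation loss are restored. Fully seeded: identical seeds give
#' identical loss curves.
#'
#' @param model a materialised \linkS4class{RecurrentUNet}.
#' @param train_set,val_set disjoint lists of samples from
#'   \code{\link{buildTrainingSet}}.
#' @param config a \linkS4class{TrainConfig}.
#' @param preset an \linkS4class{AnatomyPreset}.
#' @param weights a \linkS4class{LossWeights}.
#' @param extractor feature extractor (needed if the feature weight > 0).
#' @param verbose print per-epoch losses.
#' @return list with the trained \code{model}, a \code{history}
#'   data.frame (epoch, training loss, validation loss) and
#'   \code{best_epoch}.
#' @export
trainModel <- function(model, train_set, val_set, config = trainConfig(),
                       preset = anatomyPreset("knee"),
                       weights = lossWeights(1, 100, 1, 0.1),
                       extractor = NULL, verbose = FALSE) {
  if (!length(train_set)) stop("empty training set")
  if (!length(val_set)) stop("empty validation set")
  if (weights@feature > 0 && is.null(extractor))
    extractor <- randomFeatureExtractor()
  # optimiser-owned buffers: the C++ Adam step updates these in place
  params <- deepCopyParams(model@params)
  mbuf <- lapply(params, function(p) array(0, dim(as.array(p))))
  vbuf <- lapply(params, function(p) array(0, dim(as.array(p))))
  tstep <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  withSeed(config@seed, {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample(seq_along(train_set))
      tl <- 0
      nb <- 0L
      acc <- NULL
      for (ii in seq_along(ord)) {
        s <- augmentSample(train_set[[ord[ii]]], config@augTranslate,
                           config@augRotate)
        model@params <- params
        r <- sampleLoss(model, s, preset, weights, extractor, gradient = TRUE)
        tl <- tl + r$loss
        acc <- if (is.null(acc)) r$grads else
          Map(function(a, b) a + b, acc, r$grads)
        nb <- nb + 1L
        if (nb == config@batchSize || ii == length(ord)) {
          if (nb > 1L) acc <- lapply(acc, function(g) g / nb)
          if (is.finite(config@gradClip)) {
            gn <- sqrt(sum(vapply(acc, function(g) sum(g * g), numeric(1))))
            if (gn > config@gradClip)
              acc <- lapply(acc, function(g) g * (config@gradClip / gn))
          }
          tstep <- tstep + 1L
          # linear warmup to the configured rate keeps the first coherent
          # updates from overshooting the sigmoid losses' sensitive band
          lr <- config@learningRate * min(1, tstep / 25)
          if (config@lrSchedule == "cosine" && config@maxEpochs > 1L)
            lr <- lr * (0.05 + 0.95 * 0.5 *
                          (1 + cos(pi * (epoch - 1) / (config@maxEpochs - 1))))
          .cppAdamStep(params, acc, mbuf, vbuf, tstep, lr, 0.9, 0.999, 1e-8)
          acc <- NULL; nb <- 0L
        }
      }
      model@params <- params
      vl <- mean(vapply(val_set, function(s)
        sampleLoss(model, s, preset, weights, extractor)$loss, numeric(1)))
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = tl / length(ord),
                                     val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        tl / length(ord), vl))
      if (vl < best$loss) best <- list(loss = vl,
                                       params = deepCopyParams(params),
                                       epoch = epoch)
      if (epoch - best$epoch >= config@patience) break
    }
  })
  model@params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch)
}

#' Random hyperparameter search over loss weights
#'
#' Samples loss-weight vectors uniformly within the anatomy's search
#' ranges, trains a fresh network for a small number of epochs per
#' candidate, and scores each candidate on the validation set by ROI
#' NRMSE and ROI Pearson correlation. The winner minimises the rank sum
#' of NRMSE (ascending) and Pearson r (descending).
#'
#' @param train_set,val_set sample lists as in \code{\link{trainModel}}.
#' @param preset an \linkS4class{AnatomyPreset} (supplies the ranges).
#' @param model_config \linkS4class{ModelConfig} for the candidate models.
#' @param iterations number of sampled weight vectors.
#' @param epochs_per_iteration training epochs per candidate.
#' @param config base \linkS4class{TrainConfig}.
#' @param extractor feature extractor for the feature component.
#' @param seed RNG seed for the weight sampling.
#' @return list with \code{best} (a \linkS4class{LossWeights}) and a
#'   \code{results} data.frame of all candidates.
#' @export
hyperparameterSearch <- function(train_set, val_set,
                                 preset = anatomyPreset("knee"),
                                 model_config = modelConfig("reduced"),
                                 iterations = 15L,
                                 epochs_per_iteration = 10L,
                                 config = trainConfig(),
                                 extractor = randomFeatureExtractor(),
                                 seed = 1L) {
  rg <- preset@weightRanges
  draws <- withSeed(seed, data.frame(
    l1 = runif(iterations, rg$l1[1], rg$l1[2]),
    l1_roi = runif(iterations, rg$l1_roi[1], rg$l1_roi[2]),
    ssim = runif(iterations, rg$ssim[1], rg$ssim[2]),
    feature = runif(iterations, rg$feature[1], rg$feature[2])))
  res <- draws
  res$nrmse <- NA_real_; res$pearson <- NA_real_
  for (i in seq_len(iterations)) {
    w <- lossWeights(draws$l1[i], draws$l1_roi[i], draws$ssim[i],
                     draws$feature[i])
    cfg_i <- trainConfig(config@learningRate, config@batchSize,
                         max_epochs = epochs_per_iteration,
                         patience = epochs_per_iteration,
                         aug_translate = config@augTranslate,
                         aug_rotate = config@augRotate,
                         grad_clip = config@gradClip,
                         seed = deriveSeed(seed, i))
    model <- buildModel(model_config, seed = deriveSeed(seed, 100L + i))
    fit <- trainModel(model, train_set, val_set, cfg_i, preset, w,
                      extractor = extractor)
    stats <- vapply(val_set, function(s) {
      y <- netForward(fit$model, s$x)
      c(roiNrmse(s$y, y, s$roi),
        suppressWarnings(pearsonRoi(s$y, y, s$roi)$r))
    }, numeric(2))
    res$nrmse[i] <- mean(stats[1, ])
    res$pearson[i] <- mean(stats[2, ], na.rm = TRUE)
  }
  score <- rank(res$nrmse) + rank(-res$pearson)
  best <- which.min(score)
  list(best = lossWeights(res$l1[best], res$l1_roi[best], res$ssim[best],
                          res$feature[best]),
       results = res)
}
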