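#' Sigmoid weighting parameters
#'
#' @param xl,xh low/high T2 limits (ms) of the transition band.
#' @param yl,yh low/high weighting values.
#' @return a \linkS4class{SigmoidParams}.
#' @export
sigmoidParams <- function(xl, xh, yl, yh)
  new("SigmoidParams", xl = xl, xh = xh, yl = yl, yh = yh)

#' Loss component weights
#'
#' @param l1,l1_roi,ssim,feature non-negative weights of the global scaled
#'   L1, ROI-specific scaled L1, SSIM and feature losses.
#' @return a \linkS4class{LossWeights}.
#' @export
lossWeights <- function(l1 = 1, l1_roi = 0, ssim = 0, feature = 0)
  new("LossWeights", l1 = l1, l1Roi = l1_roi, ssim = ssim, feature = feature)

#' Per-anatomy loss and scaling presets
#'
#' Returns the sigmoid operator parameters, the hyperparameter-search
#' ranges for the loss weights, the per-slice signal-scaling target and
#' the acquisition echo times for one of the three supported anatomies.
#'
#' @param anatomy "knee", "hip" or "spine".
#' @return an \linkS4class{AnatomyPreset}.
#' @export
anatomyPreset <- function(anatomy = c("knee", "hip", "spine")) {
  anatomy <- match.arg(anatomy)
  sig <- switch(anatomy,
    knee  = sigmoidParams(0, 100, 0.1, 1.0),
    hip   = sigmoidParams(0, 60, 0.5, 1.0),
    spine = sigmoidParams(0, 150, 0.25, 1.0))
  ranges <- switch(anatomy,
    knee  = list(l1 = c(1, 1), l1_roi = c(50, 150), ssim = c(0, 2),
                 feature = c(0, 0.5)),
    hip   = list(l1 = c(1, 1), l1_roi = c(0, 3), ssim = c(0, 2),
                 feature = c(0, 1)),
    spine = list(l1 = c(1, 1), l1_roi = c(1, 10), ssim = c(10, 100),
                 feature = c(5, 55)))
  target <- switch(anatomy, knee = 500, spine = 500, hip = 100)
  te <- switch(anatomy,
    knee  = c(0, 12.9, 25.7, 51.4),
    hip   = c(0, 10.4, 20.8, 41.7),
    spine = c(0, 12.9, 25.7, 51.4))
  new("AnatomyPreset", anatomy = anatomy, sigmoid = sig,
      weightRanges = ranges, signalTarget = target, echoTimes = te)
}

#' Translated and scaled sigmoid operator
#'
#' S(x) = y_l + (y_h - y_l) * (1 + exp(-(10/(x_h - x_l)) *
#' (x - (x_l + x_h)/2)))^-1. Strictly increasing with open range
#' (y_l, y_h); it up-weights errors at high T2 in the L1 losses.
#'
#' @param x T2 value, vector or map (ms).
#' @param p a \linkS4class{SigmoidParams}.
#' @return scaled values, same shape as \code{x}.
#' @export
sigmoidScale <- function(x, p) {
  stopifnot(is(p, "SigmoidParams"))
  k <- 10 / (p@xh - p@xl)
  p@yl + (p@yh - p@yl) / (1 + exp(-k * (x - (p@xl + p@xh) / 2)))
}

sigmoidScaleGrad <- function(x, p) {
  k <- 10 / (p@xh - p@xl)
  s <- 1 / (1 + exp(-k * (x - (p@xl + p@xh) / 2)))
  (p@yh - p@yl) * k * s * (1 - s)
}

#' Scaled L1 losses
#'
#' Mean absolute difference of sigmoid-scaled T2 maps, either over all
#' pixels (\code{l1ScaledLoss}) or restricted to the tissue of interest
#' (\code{roiL1ScaledLoss}). The mean reduction keeps weight ranges
#' comparable across image sizes.
#'
#' @param t2_true,t2_pred T2 maps (ms), identical shape.
#' @param p a \linkS4class{SigmoidParams}.
#' @param roi logical or integer mask; positive/TRUE marks the tissue of
#'   interest.
#' @return scalar loss.
#' @export
l1ScaledLoss <- function(t2_true, t2_pred, p) {
  if (!identical(dim(t2_true), dim(t2_pred)) &&
      length(t2_true) != length(t2_pred))
    stop("map shapes differ")
  mean(abs(sigmoidScale(t2_true, p) - sigmoidScale(t2_pred, p)))
}

#' @rdname l1ScaledLoss
#' @export
roiL1ScaledLoss <- function(t2_true, t2_pred, roi, p) {
  sel <- roi > 0
  if (!any(sel)) stop("empty ROI: segmentation mask marks no tissue")
  mean(abs(sigmoidScale(t2_true[sel], p) - sigmoidScale(t2_pred[sel], p)))
}

l1ScaledGrad <- function(t2_true, t2_pred, p, roi = NULL) {
  g <- array(0, dim(as.array(t2_pred)))
  sel <- if (is.null(roi)) rep(TRUE, length(t2_pred)) else roi > 0
  n <- sum(sel)
  st <- sigmoidScale(t2_true[sel], p)
  sp <- sigmoidScale(t2_pred[sel], p)
  g[sel] <- sign(sp - st) * sigmoidScaleGrad(t2_pred[sel], p) / n
  g
}

## ---- SSIM ------------------------------------------------------------------

gaussianWindow <- function(size = 7, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

convValid <- function(img, w) {
  x <- array(img, c(dim(img), 1L))
  out <- .cppConvFwdD(x, array(w, c(dim(w), 1L, 1L)), 0, 1L, 0L)
  out[, , 1]
}

convFull <- function(img, w) {
  x <- array(img, c(dim(img), 1L))
  wf <- w[rev(seq_len(nrow(w))), rev(seq_len(ncol(w))), drop = FALSE]
  out <- .cppConvFwdD(x, array(wf, c(dim(w), 1L, 1L)), 0, 1L,
                      as.integer(nrow(w) - 1L))
  out[, , 1]
}

ssimCore <- function(t2_true, t2_pred, dynamic_range, grad = FALSE) {
  w <- gaussianWindow()
  C1 <- 0.01^2; C2 <- 0.03^2
  clip <- function(v) pmin(pmax(v, 0), dynamic_range) / dynamic_range
  X <- clip(t2_pred); Y <- clip(t2_true)
  mx <- convValid(X, w); my <- convValid(Y, w)
  vx <- convValid(X * X, w) - mx^2
  vy <- convValid(Y * Y, w) - my^2
  cxy <- convValid(X * Y, w) - mx * my
  A1 <- 2 * mx * my + C1; A2 <- 2 * cxy + C2
  B1 <- mx^2 + my^2 + C1; B2 <- vx + vy + C2
  smap <- (A1 * A2) / (B1 * B2)
  loss <- 1 - mean(smap)
  if (!grad) return(list(loss = loss))
  P <- length(smap)
  d_mu <- (2 * my * A2) / (B1 * B2) - (smap * 2 * mx) / B1
  d_vx <- -smap / B2
  d_cxy <- 2 * A1 / (B1 * B2)
  D1 <- d_mu - 2 * mx * d_vx - my * d_cxy
  gX <- convFull(D1, w) + 2 * X * convFull(d_vx, w) + Y * convFull(d_cxy, w)
  inside <- t2_pred > 0 & t2_pred < dynamic_range
  g <- -(gX / P) * inside / dynamic_range
  list(loss = loss, grad = g)
}

#' SSIM loss
#'
#' 1 minus the mean structural similarity index between two T2 maps. Maps
#' are clipped to \code{[0, dynamic_range]} (default 1.5x the knee sigmoid
#' upper limit) and rescaled to [0, 1]; local statistics use a 7x7
#' Gaussian window (sigma 1.5) over the valid interior, with the standard
#' stabilisation constants C1 = 0.01^2, C2 = 0.03^2.
#'
#' @param t2_true,t2_pred T2 maps (ms), identical shape, at least 7x7.
#' @param dynamic_range declared T2 dynamic range in ms.
#' @return scalar loss in [0, 1] for non-negative maps.
#' @export
ssimLoss <- function(t2_true, t2_pred, dynamic_range = 150) {
  if (!identical(dim(t2_true), dim(t2_pred))) stop("map shapes differ")
  ssimCore(t2_true, t2_pred, dynamic_range)$loss
}

## ---- combined network loss -------------------------------------------------

#' Multi-component network training loss
#'
#' Weighted sum of the four training-loss components: global scaled L1,
#' ROI-specific scaled L1, SSIM loss and perceptual feature loss. Any
#' subset of weights may be zero, reproducing the ablation
#' configurations; zero-weight components are skipped.
#'
#' @param t2_true,t2_pred T2 maps (ms), identical shape.
#' @param roi tissue-of-interest mask (required if the ROI weight is > 0).
#' @param preset an \linkS4class{AnatomyPreset} supplying the sigmoid
#'   parameters and the SSIM/feature dynamic range.
#' @param weights a \linkS4class{LossWeights}.
#' @param extractor feature extractor from
#'   \code{\link{randomFeatureExtractor}} (required if the feature weight
#'   is > 0).
#' @param gradient if TRUE, also return the analytic gradient of the total
#'   loss with respect to \code{t2_pred}.
#' @return list with \code{total}, per-component values, and optionally
#'   \code{grad}.
#' @export
networkLoss <- function(t2_true, t2_pred, roi = NULL,
                        preset = anatomyPreset("knee"),
                        weights = lossWeights(1, 100, 1, 0.1),
                        extractor = NULL, gradient = FALSE) {
  p <- preset@sigmoid
  dr <- 1.5 * p@xh
  comp <- c(l1 = 0, l1_roi = 0, ssim = 0, feature = 0)
  g <- if (gradient) array(0, dim(as.array(t2_pred))) else NULL

  if (weights@l1 > 0) {
    comp["l1"] <- l1ScaledLoss(t2_true, t2_pred, p)
    if (gradient) g <- g + weights@l1 * l1ScaledGrad(t2_true, t2_pred, p)
  }
  if (weights@l1Roi > 0) {
    if (is.null(roi)) stop("ROI weight > 0 but no ROI mask supplied")
    comp["l1_roi"] <- roiL1ScaledLoss(t2_true, t2_pred, roi, p)
    if (gradient)
      g <- g + weights@l1Roi * l1ScaledGrad(t2_true, t2_pred, p, roi)
  }
  if (weights@ssim > 0) {
    s <- ssimCore(t2_true, t2_pred, dr, grad = gradient)
    comp["ssim"] <- s$loss
    if (gradient) g <- g + weights@ssim * s$grad
  }
  if (weights@feature > 0) {
    if (is.null(extractor)) stop("feature weight > 0 but no extractor supplied")
    f <- featureLossCore(t2_true, t2_pred, extractor, dr, grad = gradient)
    comp["feature"] <- f$loss
    if (gradient) g <- g + weights@feature * f$grad
  }
  total <- weights@l1 * comp["l1"] + weights@l1Roi * comp["l1_roi"] +
    weights@ssim * comp["ssim"] + weights@feature * comp["feature"]
  out <- list(total = unname(total), components = comp)
  if (gradient) out$grad <- g
  out
}
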