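#' Perceptual feature extractor for the feature loss
#'
#' The feature loss compares deep convolutional feature maps of the true
#' and predicted T2 maps after resizing to 224 x 224, channel-tripling and
#' per-channel normalisation (means 0.485/0.456/0.406, standard deviations
#' 0.229/0.224/0.225). The extractor is dependency-injected: this
#' constructor builds a fixed-seed random convolutional stack (3 -> 8 -> 16
#' channels, two stride-2 stages) that exposes the same interface as a
#' pretrained deep feature extractor and is bit-reproducible from its
#' seed, so the loss requires no external weight files. A user-supplied
#' extractor can be plugged into \code{\link{featureLoss}} instead by
#' providing the same structure.
#'
#' @param seed RNG seed for the weight draw.
#' @return a list of class "featureExtractor".
#' @export
randomFeatureExtractor <- function(seed = 17L) {
  shapes <- list(c(3L, 3L, 3L, 8L), c(3L, 3L, 8L, 16L), c(3L, 3L, 16L, 16L))
  strides <- c(2L, 2L, 1L)
  withSeed(seed, {
    weights <- lapply(shapes, function(s) {
      fan_in <- prod(s[1:3])
      array(rnorm(prod(s), sd = sqrt(2 / fan_in)), s)
    })
  })
  structure(list(weights = weights, strides = strides, size = 224L,
                 means = c(0.485, 0.456, 0.406),
                 sds = c(0.229, 0.224, 0.225), seed = as.integer(seed)),
            class = "featureExtractor")
}

## forward pass caching activations for the backward pass
featForward <- function(x, ex) {
  acts <- list(x)
  n <- length(ex$weights)
  for (l in seq_len(n)) {
    w <- ex$weights[[l]]
    x <- .cppConvFwdD(x, w, rep(0, dim(w)[4]), ex$strides[l], 1L)
    if (l < n) x <- pmax(x, 0)
    acts[[l + 1L]] <- x
  }
  acts
}

featBackward <- function(acts, dtop, ex) {
  n <- length(ex$weights)
  g <- dtop
  for (l in rev(seq_len(n))) {
    if (l < n) g <- g * (acts[[l + 1L]] > 0)
    g <- .cppConvBwdDataD(dim(acts[[l]]), ex$weights[[l]], g,
                          ex$strides[l], 1L)
  }
  g
}

featureLossCore <- function(t2_true, t2_pred, extractor, dynamic_range,
                            grad = FALSE) {
  sz <- extractor$size
  Rr <- resizeMatrix(nrow(as.matrix(t2_pred)), sz)
  Rc <- resizeMatrix(ncol(as.matrix(t2_pred)), sz)
  prep <- function(map) {
    m01 <- pmin(pmax(map, 0), dynamic_range) / dynamic_range
    resized <- Rr %*% m01 %*% t(Rc)
    x <- array(0, c(sz, sz, 3L))
    for (c in 1:3)
      x[, , c] <- (resized - extractor$means[c]) / extractor$sds[c]
    x
  }
  ax <- featForward(prep(t2_pred), extractor)
  ay <- featForward(prep(t2_true), extractor)
  fx <- ax[[length(ax)]]; fy <- ay[[length(ay)]]
  loss <- mean(abs(fx - fy))
  if (!grad) return(list(loss = loss))
  dtop <- sign(fx - fy) / length(fx)
  din <- featBackward(ax, dtop, extractor)
  dres <- matrix(0, sz, sz)
  for (c in 1:3) dres <- dres + din[, , c] / extractor$sds[c]
  d01 <- t(Rr) %*% dres %*% Rc
  inside <- t2_pred > 0 & t2_pred < dynamic_range
  list(loss = loss, grad = d01 * inside / dynamic_range)
}

#' Perceptual feature loss
#'
#' Mean absolute difference of deep convolutional features of the true and
#' predicted T2 maps (resized, channel-tripled and normalised as described
#' in \code{\link{randomFeatureExtractor}}). Encourages retention of
#' sharper textures that pixel losses under-penalise.
#'
#' @param t2_true,t2_pred T2 maps (ms), identical shape.
#' @param extractor a feature extractor; defaults to the fixed-seed random
#'   convolutional stack.
#' @param dynamic_range declared T2 dynamic range (ms) used to map T2 onto
#'   image intensities.
#' @return scalar loss (>= 0; 0 for identical maps).
#' @export
featureLoss <- function(t2_true, t2_pred, extractor = randomFeatureExtractor(),
                        dynamic_range = 150) {
  if (is.null(extractor)) stop("no feature extractor supplied")
  if (!identical(dim(as.matrix(t2_true)), dim(as.matrix(t2_pred))))
    stop("map shapes differ")
  featureLossCore(as.matrix(t2_true), as.matrix(t2_pred), extractor,
                  dynamic_range)$loss
}
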