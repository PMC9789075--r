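#' EchoSeries: a multi-echo magnitude image stack
#'
#' Container for a stack of magnitude images acquired at several echo times,
#' the unit consumed by the undersampler and the T2 fitter. Voxel data are a
#' 4-D array ordered (y, x, z, echo): y is the in-plane phase-encode axis,
#' x the fully-sampled readout, z the slice (second phase-encode) axis.
#'
#' @slot data numeric 4-D array (n_y, n_x, n_z, n_echoes) of magnitudes.
#' @slot echoTimes numeric vector of echo times in ms, strictly increasing,
#'   starting at 0.
#' @export
setClass("EchoSeries",
  representation(data = "array", echoTimes = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4-D (y, x, z, echo) array")
    te <- object@echoTimes
    if (d[4] != length(te)) return("one image volume per echo time required")
    if (length(te) && te[1] != 0) return("first echo time must be 0 ms")
    if (any(diff(te) <= 0)) return("echo times must be strictly increasing")
    if (any(object@data < 0)) return("magnitude data must be non-negative")
    TRUE
  })

#' RoiMask: labelled tissue-of-interest voxels
#'
#' Integer label volume marking tissue compartments (cartilage arcs,
#' intervertebral discs). 0 is background; positive integers index
#' compartments.
#'
#' @slot labels integer 3-D array (y, x, z).
#' @export
setClass("RoiMask",
  representation(labels = "array"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be 3-D")
    if (any(object@labels < 0)) return("labels must be non-negative")
    TRUE
  })

#' PhantomTruth: a synthetic acquisition with known ground truth
#'
#' @slot t2 numeric 3-D array of ground-truth T2 (ms); NA outside tissue.
#' @slot pd numeric 3-D array of proton density (a.u.).
#' @slot roi \linkS4class{RoiMask} of tissue-of-interest compartments.
#' @slot echoes \linkS4class{EchoSeries} simulated from the truth maps.
#' @slot config list, the \code{\link{phantomConfig}} used.
#' @export
setClass("PhantomTruth",
  representation(t2 = "array", pd = "array", roi = "RoiMask",
                 echoes = "EchoSeries", config = "list"),
  validity = function(object) {
    d <- dim(object@pd)
    if (!identical(dim(object@t2), d)) return("t2/pd dimension mismatch")
    if (!identical(dim(object@roi@labels), d)) return("roi dimension mismatch")
    tissue <- object@pd > 0
    if (any(object@roi@labels > 0 & !tissue))
      return("ROI voxels must lie inside tissue (pd > 0)")
    if (any(tissue & !(object@t2 > 0), na.rm = TRUE) ||
        anyNA(object@t2[tissue]))
      return("t2 must be positive wherever pd > 0")
    TRUE
  })

#' SamplingPlan: target geometry of an accelerated acquisition
#'
#' @slot R target acceleration factor relative to elliptical coverage.
#' @slot ellipseAreaFraction fraction of the rectangular ky-kz grid covered
#'   by the acquisition ellipse (default 0.7).
#' @slot centralSquareAreaFraction area fraction of the fully-sampled
#'   central region (default 0.05).
#' @slot grid integer c(n_ky, n_kz).
#' @slot nEchoes number of echo images, each undersampled with its own mask.
#' @slot seed integer RNG seed; echo e uses a deterministic offset of it.
#' @slot calibrationTolerance relative tolerance on realised R (default 0.02).
#' @slot alpha linear growth rate of the Poisson-disc exclusion radius with
#'   normalised elliptical radius (default 2).
#' @export
setClass("SamplingPlan",
  representation(R = "numeric", ellipseAreaFraction = "numeric",
                 centralSquareAreaFraction = "numeric", grid = "integer",
                 nEchoes = "integer", seed = "integer",
                 calibrationTolerance = "numeric", alpha = "numeric"),
  validity = function(object) {
    if (object@R < 1) return("R must be >= 1")
    f <- object@ellipseAreaFraction
    if (f <= 0 || f > 1) return("ellipseAreaFraction must be in (0, 1]")
    cs <- object@centralSquareAreaFraction
    if (cs <= 0 || cs >= f)
      return("centralSquareAreaFraction must be in (0, ellipseAreaFraction)")
    if (length(object@grid) != 2L || any(object@grid < 4L))
      return("grid must be two extents >= 4")
    if (object@calibrationTolerance <= 0) return("tolerance must be positive")
    TRUE
  })

#' SamplingMask: realised per-echo ky-kz sampling patterns
#'
#' @slot masks logical 3-D array (n_ky, n_kz, n_echoes).
#' @slot support logical matrix, the elliptical acquisition support.
#' @slot realizedR numeric, realised acceleration per echo (ellipse points /
#'   sampled points).
#' @slot plan the \linkS4class{SamplingPlan} that produced the masks.
#' @export
setClass("SamplingMask",
  representation(masks = "array", support = "matrix", realizedR = "numeric",
                 plan = "SamplingPlan"),
  validity = function(object) {
    d <- dim(object@masks)
    if (length(d) != 3L) return("masks must be (ky, kz, echo)")
    if (!identical(d[1:2], dim(object@support)))
      return("mask/support dimension mismatch")
    if (d[3] != length(object@realizedR))
      return("one realised R per echo required")
    for (e in seq_len(d[3]))
      if (any(object@masks[, , e] & !object@support))
        return("sampled points must lie inside the elliptical support")
    TRUE
  })

#' T2Map: per-voxel mono-exponential fit results
#'
#' @slot t2 numeric array of fitted T2 (ms); NA where the fit is invalid.
#' @slot amplitude numeric array of fitted signal amplitude (a.u.).
#' @slot valid logical array: above-floor voxels with a usable fit.
#' @slot atBound logical array: voxels clamped to a T2 bound (degenerate or
#'   non-decaying signal).
#' @slot bounds numeric c(lower, upper) T2 bounds in ms.
#' @export
setClass("T2Map",
  representation(t2 = "array", amplitude = "array", valid = "array",
                 atBound = "array", bounds = "numeric"),
  validity = function(object) {
    d <- dim(object@t2)
    if (!identical(dim(object@amplitude), d) ||
        !identical(dim(object@valid), d) ||
        !identical(dim(object@atBound), d))
      return("t2/amplitude/valid/atBound dimension mismatch")
    v <- object@valid & !object@atBound
    tv <- object@t2[v]
    if (anyNA(tv) || (length(tv) &&
        (min(tv) < object@bounds[1] - 1e-9 ||
         max(tv) > object@bounds[2] + 1e-9)))
      return("valid T2 values must lie within bounds")
    TRUE
  })

#' SigmoidParams: the translated and scaled sigmoid weighting operator
#'
#' Parameters of S(x) = y_l + (y_h - y_l) / (1 + exp(-(10/(x_h - x_l)) *
#' (x - (x_l + x_h)/2))), which up-weights high T2 values in the L1 losses.
#'
#' @slot xl,xh low/high T2 limits (ms) of the transition band.
#' @slot yl,yh low/high weighting values.
#' @export
setClass("SigmoidParams",
  representation(xl = "numeric", xh = "numeric", yl = "numeric",
                 yh = "numeric"),
  validity = function(object) {
    if (object@xl >= object@xh) return("xl must be < xh")
    if (object@yl <= 0 || object@yl > object@yh)
      return("need 0 < yl <= yh")
    TRUE
  })

#' LossWeights: weights of the four training-loss components
#'
#' @slot l1 global scaled-L1 weight.
#' @slot l1Roi ROI-specific scaled-L1 weight.
#' @slot ssim SSIM-loss weight.
#' @slot feature perceptual feature-loss weight.
#' @export
setClass("LossWeights",
  representation(l1 = "numeric", l1Roi = "numeric", ssim = "numeric",
                 feature = "numeric"),
  validity = function(object) {
    w <- c(object@l1, object@l1Roi, object@ssim, object@feature)
    if (any(w < 0)) return("weights must be non-negative")
    if (all(w == 0)) return("at least one weight must be positive")
    TRUE
  })

#' AnatomyPreset: per-anatomy loss parameters and scaling targets
#'
#' @slot anatomy "knee", "hip" or "spine".
#' @slot sigmoid \linkS4class{SigmoidParams} for the anatomy.
#' @slot weightRanges list of c(lo, hi) search ranges per loss component.
#' @slot signalTarget upper end of the per-slice signal-scaling range (a.u.).
#' @slot echoTimes acquisition echo times (ms).
#' @export
setClass("AnatomyPreset",
  representation(anatomy = "character", sigmoid = "SigmoidParams",
                 weightRanges = "list", signalTarget = "numeric",
                 echoTimes = "numeric"))

#' ModelConfig: architecture configuration of the T2-prediction network
#'
#' @slot variant "full", "no_rnn" or "reduced".
#' @slot nEchoes number of echo-image input channels (4).
#' @slot streamDepths per-echo processing-stream layer depths.
#' @slot encoderDepths UNet encoder depths (3x3 stride-2 convolutions).
#' @slot decoderDepths list with transpose-convolution output depths
#'   (\code{tconv}) and refinement-convolution depths (\code{conv}).
#' @slot lambdaW inter-stream residual weighting (default 0.2).
#' @slot streamDirection "forward" (earlier to later echo) or "backward".
#' @export
setClass("ModelConfig",
  representation(variant = "character", nEchoes = "integer",
                 streamDepths = "integer", encoderDepths = "integer",
                 decoderDepths = "list", lambdaW = "numeric",
                 streamDirection = "character", inputScale = "numeric"),
  validity = function(object) {
    if (!object@variant %in% c("full", "no_rnn", "reduced"))
      return("variant must be full, no_rnn or reduced")
    if (object@nEchoes < 1) return("nEchoes must be positive")
    TRUE
  })

#' RecurrentUNet: an instantiated network
#'
#' @slot config \linkS4class{ModelConfig}.
#' @slot params named list of weight/bias arrays (empty until materialised).
#' @export
setClass("RecurrentUNet",
  representation(config = "ModelConfig", params = "list"))

#' TrainConfig: optimisation protocol
#'
#' @slot learningRate Adam learning rate (default 0.001).
#' @slot batchSize training batch size (default 1).
#' @slot maxEpochs upper bound on training epochs.
#' @slot patience early-stopping patience on validation loss (default 10).
#' @slot augTranslate max |in-plane translation| in pixels (default 10).
#' @slot augRotate max |rotation| about the slice axis in degrees (default 5).
#' @slot seed RNG seed controlling initialisation and augmentation.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 maxEpochs = "integer", patience = "integer",
                 augTranslate = "numeric", augRotate = "numeric",
                 gradClip = "numeric", lrSchedule = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@patience < 1) return("patience must be >= 1")
    if (object@augTranslate < 0 || object@augRotate < 0)
      return("augmentation bounds must be non-negative")
    TRUE
  })

## ---- show methods ----------------------------------------------------------

setMethod("show", "EchoSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("EchoSeries: %d x %d x %d voxels, %d echoes (TE = %s ms)\n",
              d[1], d[2], d[3], d[4],
              paste(object@echoTimes, collapse = ", ")))
})

setMethod("show", "SamplingMask", function(object) {
  cat(sprintf(
    "SamplingMask: %d x %d grid, %d echoes, target R = %.3g, realised R = %s\n",
    dim(object@masks)[1], dim(object@masks)[2], dim(object@masks)[3],
    object@plan@R, paste(sprintf("%.3f", object@realizedR), collapse = ", ")))
})

setMethod("show", "T2Map", function(object) {
  v <- object@t2[object@valid]
  cat(sprintf("T2Map: %s voxels, %d valid, median T2 = %.2f ms\n",
              paste(dim(object@t2), collapse = " x "), sum(object@valid),
              if (length(v)) median(v) else NA_real_))
})

setMethod("show", "RecurrentUNet", function(object) {
  cat(sprintf("RecurrentUNet (variant = %s): %s trainable parameters%s\n",
              object@config@variant,
              format(nParameters(object), big.mark = ","),
              if (length(object@params)) "" else " (not materialised)"))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth (%s): %s grid, %d ROI voxels in %d compartment(s)\n",
    object@config$anatomy, paste(dim(object@pd), collapse = " x "),
    sum(object@roi@labels > 0), length(setdiff(unique(c(object@roi@labels)), 0L))))
})

## ---- accessors -------------------------------------------------------------

#' @describeIn EchoSeries-class echo times in ms
#' @param object an object of the documented class
#' @export
setGeneric("echoTimes", function(object) standardGeneric("echoTimes"))
#' @rdname EchoSeries-class
#' @export
setMethod("echoTimes", "EchoSeries", function(object) object@echoTimes)
#' @rdname EchoSeries-class
#' @export
setMethod("echoTimes", "PhantomTruth",
          function(object) object@echoes@echoTimes)

#' @describeIn EchoSeries-class the (y, x, z, echo) voxel array
#' @export
setGeneric("echoData", function(object) standardGeneric("echoData"))
#' @rdname EchoSeries-class
#' @export
setMethod("echoData", "EchoSeries", function(object) object@data)

#' @describeIn T2Map-class fitted T2 values in ms (NA where invalid)
#' @export
setGeneric("t2Values", function(object) standardGeneric("t2Values"))
#' @rdname T2Map-class
#' @export
setMethod("t2Values", "T2Map", function(object) object@t2)
#' @rdname T2Map-class
#' @export
setMethod("t2Values", "PhantomTruth", function(object) object@t2)

#' @describeIn RoiMask-class integer compartment labels
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))
#' @rdname RoiMask-class
#' @export
setMethod("roiLabels", "RoiMask", function(object) object@labels)
#' @rdname RoiMask-class
#' @export
setMethod("roiLabels", "PhantomTruth", function(object) object@roi@labels)

#' @describeIn SamplingMask-class per-echo logical sampling masks
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname SamplingMask-class
#' @export
setMethod("maskArray", "SamplingMask", function(object) object@masks)

#' @describeIn SamplingMask-class realised acceleration factor per echo
#' @export
setGeneric("realizedR", function(object) standardGeneric("realizedR"))
#' @rdname SamplingMask-class
#' @export
setMethod("realizedR", "SamplingMask", function(object) object@realizedR)
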