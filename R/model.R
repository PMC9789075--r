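#' Network architecture configuration
#'
#' Defines the image-to-map network that predicts a T2 map from the
#' aliased echo images of one slice. Three variants are supported:
#'
#' \describe{
#'   \item{full}{A recurrent portion followed by a UNet. Each echo image
#'     passes through a 5-layer processing stream of 3x3 stride-1
#'     convolutions with layer depths 64, 128, 256, 512 and 1, the
#'     stream weights shared across echoes. 3x3 stride-1 convolutions
#'     with residual connections transfer information between temporally
#'     adjacent corresponding hidden layers, scaled by \code{lambda_w};
#'     each echo position additionally applies a learned per-channel gain
#'     to its hidden states. Residual connections link each input image to
#'     its stream output. The four stream outputs are concatenated and fed
#'     to a UNet (3x3 stride-2 convolution encoder, 4x4 stride-2
#'     transpose-convolution decoder with skip concatenation and 3x3
#'     refinement convolutions) that emits the map.}
#'   \item{no_rnn}{The UNet alone, fed the concatenated aliased images.}
#'   \item{reduced}{The full architecture with every layer depth halved
#'     except the inputs to the recurrent portion and the UNet.}
#' }
#'
#' With the default depths the trainable parameter counts are
#' 39,808,710 (full), 35,116,037 (no_rnn) and 9,958,246 (reduced).
#'
#' @param variant "full", "no_rnn" or "reduced".
#' @param n_echoes number of echo-image input channels.
#' @param lambda_w inter-stream residual weighting (default 0.2).
#' @param stream_direction "forward" passes hidden state from earlier to
#'   later echoes (earlier echoes carry more signal), "backward" reverses.
#' @param input_scale fixed multiplicative prescale applied to the input
#'   images inside the network so that activations, and with them the
#'   network's output sensitivity to a coherent optimiser step, are well
#'   conditioned for the sigmoid-weighted losses. Has no trainable
#'   parameters.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(variant = c("full", "no_rnn", "reduced"),
                        n_echoes = 4L, lambda_w = 0.2,
                        stream_direction = c("forward", "backward"),
                        input_scale = 1 / 5000) {
  variant <- match.arg(variant)
  stream_direction <- match.arg(stream_direction)
  half <- variant == "reduced"
  hv <- function(x) if (half) pmax(1L, x %/% 2L) else x
  new("ModelConfig", variant = variant, nEchoes = as.integer(n_echoes),
      streamDepths = hv(c(64L, 128L, 256L, 512L)),
      encoderDepths = hv(c(64L, 128L, 256L, 512L, 1024L)),
      decoderDepths = list(tconv = hv(c(1024L, 384L, 48L, 32L, 68L)),
                           conv = hv(c(512L, 192L, 128L, 116L, 142L))),
      lambdaW = lambda_w, streamDirection = stream_direction,
      inputScale = input_scale)
}

## Named list of parameter array dimensions for a configuration.
modelParamShapes <- function(config) {
  sh <- list()
  E <- config@nEchoes
  if (config@variant != "no_rnn") {
    d <- c(1L, config@streamDepths, 1L)      # stream: 1 -> depths -> 1
    for (l in seq_len(length(d) - 1L)) {
      sh[[paste0("stream_w", l)]] <- c(3L, 3L, d[l], d[l + 1L])
      sh[[paste0("stream_b", l)]] <- d[l + 1L]
    }
    for (l in seq_along(config@streamDepths)) {
      dl <- config@streamDepths[l]
      sh[[paste0("inter_w", l)]] <- c(3L, 3L, dl, dl)
      sh[[paste0("inter_b", l)]] <- dl
      sh[[paste0("gain", l)]] <- c(dl, E)
    }
  }
  enc <- config@encoderDepths
  prev <- E
  for (k in seq_along(enc)) {
    sh[[paste0("enc_w", k)]] <- c(3L, 3L, prev, enc[k])
    sh[[paste0("enc_b", k)]] <- enc[k]
    prev <- enc[k]
  }
  tc <- config@decoderDepths$tconv
  cc <- config@decoderDepths$conv
  # the last decoder level concatenates the full-resolution UNet input
  skips <- c(rev(enc[-length(enc)]), E)
  for (k in seq_along(tc)) {
    # transpose-conv weights are stored (kh, kw, out, in)
    sh[[paste0("dec_t_w", k)]] <- c(4L, 4L, tc[k], prev)
    sh[[paste0("dec_t_b", k)]] <- tc[k]
    sh[[paste0("dec_c_w", k)]] <- c(3L, 3L, tc[k] + skips[k], cc[k])
    sh[[paste0("dec_c_b", k)]] <- cc[k]
    prev <- cc[k]
  }
  sh[["head_w"]] <- c(3L, 3L, prev, 1L)
  sh[["head_b"]] <- 1L
  sh
}

#' Build a network
#'
#' Instantiates a \linkS4class{RecurrentUNet} for a configuration. With
#' \code{materialise = FALSE} only the layer description is kept (enough
#' for parameter counting); otherwise weights are drawn with seeded
#' He-normal initialisation, biases start at zero and per-echo channel
#' gains at one.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param seed RNG seed for the weight draw.
#' @param materialise whether to allocate and initialise the weights.
#' @return a \linkS4class{RecurrentUNet}.
#' @export
buildModel <- function(config, seed = 1L, materialise = TRUE) {
  params <- list()
  if (materialise) {
    shapes <- modelParamShapes(config)
    withSeed(seed, {
      params <- lapply(names(shapes), function(nm) {
        s <- shapes[[nm]]
        if (startsWith(nm, "gain")) return(array(1, s))
        if (identical(nm, "head_b")) return(30)   # start near tissue T2 (ms)
        if (length(s) == 1L) return(numeric(s))
        fan_in <- if (startsWith(nm, "dec_t_w")) s[1] * s[2] * s[4] / 4
                  else prod(s[1:3])
        sd <- sqrt(2 / fan_in)
        # small head weights keep initial predictions inside the sigmoid
        # operator's sensitive band instead of its saturated tails
        if (identical(nm, "head_w")) sd <- sd / 50
        array(rnorm(prod(s), sd = sd), s)
      })
    })
    names(params) <- names(shapes)
  }
  new("RecurrentUNet", config = config, params = params)
}

#' Number of trainable parameters
#'
#' @param object a \linkS4class{RecurrentUNet} or \linkS4class{ModelConfig}.
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname nParameters
#' @export
setMethod("nParameters", "ModelConfig", function(object)
  sum(vapply(modelParamShapes(object), prod, numeric(1))))

#' @rdname nParameters
#' @export
setMethod("nParameters", "RecurrentUNet", function(object)
  nParameters(object@config))

## leaky rectifier: keeps a small negative-slope path so units cannot die
## irrecoverably during the aggressive early phase of batch-1 training
relu <- function(x) { neg <- x < 0; x[neg] <- 0.01 * x[neg]; x }
reluGrad <- function(pre) 1 - 0.99 * (pre < 0)

## Forward pass for one slice. x: (H, W, n_echoes). Returns the predicted
## map; with tape = TRUE also every activation needed for the backward pass.
netForward <- function(model, x, tape = FALSE) {
  cfg <- model@config
  P <- model@params
  if (!length(P)) stop("model has no materialised weights")
  E <- cfg@nEchoes
  x <- x * cfg@inputScale
  tp <- if (tape) list() else NULL

  if (cfg@variant != "no_rnn") {
    nl <- length(cfg@streamDepths)
    ord <- if (cfg@streamDirection == "forward") seq_len(E) else rev(seq_len(E))
    outs <- vector("list", E)
    hidden_prev <- NULL
    if (tape) { tp$stream <- vector("list", E); tp$order <- ord }
    for (t in ord) {
      a <- x[, , t, drop = FALSE]
      rec <- list(input = a)
      hidden <- vector("list", nl)
      for (l in seq_len(nl)) {
        pre <- .cppConvFwd(a, P[[paste0("stream_w", l)]],
                           P[[paste0("stream_b", l)]], 1L, 1L)
        if (!is.null(hidden_prev)) {
          inter <- .cppConvFwd(hidden_prev[[l]], P[[paste0("inter_w", l)]],
                               P[[paste0("inter_b", l)]], 1L, 1L)
          pre <- pre + cfg@lambdaW * inter
        }
        r <- relu(pre)
        gl <- P[[paste0("gain", l)]][, t]
        a <- r * rep(gl, each = dim(r)[1] * dim(r)[2])
        hidden[[l]] <- a
        if (tape) { rec[[paste0("pre", l)]] <- pre; rec[[paste0("relu", l)]] <- r }
      }
      o <- .cppConvFwd(a, P[[paste0("stream_w", nl + 1L)]],
                       P[[paste0("stream_b", nl + 1L)]], 1L, 1L) +
        x[, , t, drop = FALSE]
      outs[[t]] <- o
      if (tape) { rec$hidden <- hidden; tp$stream[[t]] <- rec }
      hidden_prev <- hidden
    }
    u <- array(0, c(dim(x)[1:2], E))
    for (t in seq_len(E)) u[, , t] <- outs[[t]][, , 1]
  } else {
    u <- x
  }
  if (tape) tp$unet_in <- u

  enc <- cfg@encoderDepths
  acts <- vector("list", length(enc))
  a <- u
  for (k in seq_along(enc)) {
    a <- relu(.cppConvFwd(a, P[[paste0("enc_w", k)]],
                          P[[paste0("enc_b", k)]], 2L, 1L))
    acts[[k]] <- a
  }
  if (tape) tp$enc <- acts

  skips <- c(rev(acts[-length(acts)]), list(u))
  tc <- cfg@decoderDepths$tconv
  if (tape) tp$dec <- vector("list", length(tc))
  for (k in seq_along(tc)) {
    tpre <- .cppTConvFwd(a, P[[paste0("dec_t_w", k)]],
                         P[[paste0("dec_t_b", k)]], 2L, 1L)
    tout <- relu(tpre)
    cat_in <- if (is.null(skips[[k]])) tout else {
      d1 <- dim(tout); d2 <- dim(skips[[k]])
      arr <- array(0, c(d1[1], d1[2], d1[3] + d2[3]))
      arr[, , seq_len(d1[3])] <- tout
      arr[, , d1[3] + seq_len(d2[3])] <- skips[[k]]
      arr
    }
    cpre <- .cppConvFwd(cat_in, P[[paste0("dec_c_w", k)]],
                        P[[paste0("dec_c_b", k)]], 1L, 1L)
    cout <- relu(cpre)
    if (tape) tp$dec[[k]] <- list(dec_in = a, tout = tout, cat_in = cat_in,
                                  cout = cout)
    a <- cout
  }
  y <- .cppConvFwd(a, P$head_w, P$head_b, 1L, 1L)
  if (tape) { tp$head_in <- a; tp$y <- y[, , 1]; return(tp) }
  y[, , 1]
}

## Backward pass: gradient of the loss with respect to every parameter,
## given dL/dy. Returns a named list aligned with the parameter list.
netBackward <- function(model, x, tp, dy) {
  cfg <- model@config
  P <- model@params
  E <- cfg@nEchoes
  # gradients are allocated lazily: most layers receive exactly one
  # contribution, so zero-init plus addition would double the traffic
  G <- new.env(parent = emptyenv())
  gadd <- function(nm, val) {
    cur <- G[[nm]]
    assign(nm, if (is.null(cur)) val else cur + val, envir = G)
  }

  dyc <- array(dy, c(dim(dy), 1L))
  bw <- .cppConvBwd(tp$head_in, P$head_w, dyc, 1L, 1L, TRUE)
  gadd("head_w", bw$dw); gadd("head_b", bw$db)
  da <- bw$dx

  enc <- cfg@encoderDepths
  tc <- cfg@decoderDepths$tconv
  dskips <- vector("list", length(enc) - 1L)   # grads into encoder skips
  dskip_in <- NULL                             # grad into the full-res input
  for (k in rev(seq_along(tc))) {
    rec <- tp$dec[[k]]
    dcpre <- da * reluGrad(rec$cout)
    bw <- .cppConvBwd(rec$cat_in, P[[paste0("dec_c_w", k)]], dcpre, 1L, 1L, TRUE)
    gadd(paste0("dec_c_w", k), bw$dw)
    gadd(paste0("dec_c_b", k), bw$db)
    dcat <- bw$dx
    nt <- dim(rec$tout)[3]
    dtout <- dcat[, , seq_len(nt), drop = FALSE]
    if (dim(dcat)[3] > nt) {
      ds <- dcat[, , nt + seq_len(dim(dcat)[3] - nt), drop = FALSE]
      if (k == length(tc)) dskip_in <- ds
      else dskips[[length(enc) - k]] <- ds
    }
    dtpre <- dtout * reluGrad(rec$tout)
    bw <- .cppTConvBwd(rec$dec_in, P[[paste0("dec_t_w", k)]], dtpre, 2L, 1L, TRUE)
    gadd(paste0("dec_t_w", k), bw$dw)
    gadd(paste0("dec_t_b", k), bw$db)
    da <- bw$dx
  }

  for (k in rev(seq_along(enc))) {
    if (k < length(enc) && !is.null(dskips[[k]]))
      da <- da + dskips[[k]]
    dpre <- da * reluGrad(tp$enc[[k]])
    below <- if (k == 1L) tp$unet_in else tp$enc[[k - 1L]]
    bw <- .cppConvBwd(below, P[[paste0("enc_w", k)]], dpre, 2L, 1L, TRUE)
    gadd(paste0("enc_w", k), bw$dw)
    gadd(paste0("enc_b", k), bw$db)
    da <- bw$dx
  }
  du <- da                                   # gradient into the UNet input
  if (!is.null(dskip_in)) du <- du + dskip_in

  finish <- function() {
    out <- lapply(names(P), function(nm) {
      g <- G[[nm]]
      if (is.null(g)) array(0, dim(as.array(P[[nm]]))) else g
    })
    names(out) <- names(P)
    out
  }
  if (cfg@variant == "no_rnn") return(finish())

  nl <- length(cfg@streamDepths)
  ord <- tp$order
  dhidden_next <- NULL                       # grads flowing back along echoes
  for (ti in rev(seq_along(ord))) {
    t <- ord[ti]
    rec <- tp$stream[[t]]
    douts <- du[, , t, drop = FALSE]         # stream output grad (+ input res)
    bw <- .cppConvBwd(rec$hidden[[nl]], P[[paste0("stream_w", nl + 1L)]],
                      douts, 1L, 1L, TRUE)
    gadd(paste0("stream_w", nl + 1L), bw$dw)
    gadd(paste0("stream_b", nl + 1L), bw$db)
    dh <- vector("list", nl)
    dh[[nl]] <- bw$dx
    if (!is.null(dhidden_next))
      for (l in seq_len(nl)) {
        inter_bw <- .cppConvBwd(rec$hidden[[l]], P[[paste0("inter_w", l)]],
                                dhidden_next[[l]], 1L, 1L, TRUE)
        gadd(paste0("inter_w", l), cfg@lambdaW * inter_bw$dw)
        gadd(paste0("inter_b", l), cfg@lambdaW * inter_bw$db)
        dh[[l]] <- if (is.null(dh[[l]])) cfg@lambdaW * inter_bw$dx
                   else dh[[l]] + cfg@lambdaW * inter_bw$dx
      }
    dhidden_prev <- vector("list", nl)       # grads into previous echo hidden
    dcur <- NULL
    for (l in rev(seq_len(nl))) {
      dl_total <- dh[[l]]
      if (!is.null(dcur))
        dl_total <- if (is.null(dl_total)) dcur else dl_total + dcur
      if (is.null(dl_total)) dl_total <- array(0, dim(rec$hidden[[l]]))
      gl <- P[[paste0("gain", l)]][, t]
      hw <- dim(rec[[paste0("relu", l)]])[1] * dim(rec[[paste0("relu", l)]])[2]
      gnm <- paste0("gain", l)
      if (is.null(G[[gnm]]))
        assign(gnm, array(0, dim(P[[gnm]])), envir = G)
      G[[gnm]][, t] <- G[[gnm]][, t] +
        colSums(matrix(dl_total * rec[[paste0("relu", l)]], hw))
      drelu <- dl_total * rep(gl, each = hw)
      dpre <- drelu * reluGrad(rec[[paste0("pre", l)]])
      below <- if (l == 1L) rec$input else rec$hidden[[l - 1L]]
      bw <- .cppConvBwd(below, P[[paste0("stream_w", l)]], dpre, 1L, 1L,
                        l > 1L)
      gadd(paste0("stream_w", l), bw$dw)
      gadd(paste0("stream_b", l), bw$db)
      dcur <- if (l > 1L) bw$dx else NULL
      # contribution that flows to the PREVIOUS echo via the inter conv is
      # picked up on the previous iteration through dhidden_next
      dhidden_prev[[l]] <- dpre
    }
    dhidden_next <- dhidden_prev
  }
  finish()
}

#' Predict a T2 map from aliased echo images
#'
#' Runs the network on each slice of an aliased
#' \linkS4class{EchoSeries}. Spatial extents must be divisible by 32 (the
#' UNet halves resolution five times).
#'
#' @param model a materialised \linkS4class{RecurrentUNet}.
#' @param echoes an \linkS4class{EchoSeries} (scaled as in training) or a
#'   (H, W, n_echoes) array for a single slice.
#' @return numeric array of predicted T2 (ms): (H, W) for a single slice
#'   input, (H, W, n_slices) for a series.
#' @export
predictMap <- function(model, echoes) {
  cfg <- model@config
  one <- function(x) {
    d <- dim(x)
    if (length(d) != 3L || d[3] != cfg@nEchoes)
      stop(sprintf("expected a (H, W, %d) echo-image slice", cfg@nEchoes))
    if (d[1] %% 32L || d[2] %% 32L)
      stop("spatial extents must be divisible by 32")
    netForward(model, x)
  }
  if (is(echoes, "EchoSeries")) {
    d <- dim(echoes@data)
    out <- array(0, c(d[1], d[2], d[3]))
    for (z in seq_len(d[3])) {
      sl <- echoes@data[, , z, , drop = FALSE]
      dim(sl) <- c(d[1], d[2], d[4])
      out[, , z] <- one(sl)
    }
    out
  } else one(echoes)
}
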