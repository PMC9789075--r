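# Independent reference implementations used as oracles. All are written
# naively (direct loops, double precision) so they share no code with the
# package's optimised paths.

# direct-loop 2D convolution, zero padding; w dims (kh, kw, cin, cout)
refConvFwd <- function(x, w, b, stride, pad) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ho <- (H + 2 * pad - kh) %/% stride + 1
  wo <- (W + 2 * pad - kw) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  y <- array(0, c(ho, wo, cout))
  for (o in seq_len(cout)) {
    wo_ <- array(w[, , , o], dim(w)[1:3])
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      patch <- xp[(i - 1) * stride + seq_len(kh),
                  (j - 1) * stride + seq_len(kw), , drop = FALSE]
      y[i, j, o] <- sum(patch * wo_) + b[o]
    }
  }
  y
}

# direct-loop transpose convolution; w dims (kh, kw, cout, cin)
refTConvFwd <- function(x, w, b, stride, pad) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[3]; cin <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ho <- (H - 1) * stride + kh - 2 * pad
  wo <- (W - 1) * stride + kw - 2 * pad
  y <- array(0, c(ho, wo, cout))
  for (i in seq_len(H)) for (j in seq_len(W))
    for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      oi <- (i - 1) * stride + ki - pad
      oj <- (j - 1) * stride + kj - pad
      if (oi >= 1 && oi <= ho && oj >= 1 && oj <= wo)
        for (o in seq_len(cout))
          y[oi, oj, o] <- y[oi, oj, o] + sum(x[i, j, ] * w[ki, kj, o, ])
    }
  for (o in seq_len(cout)) y[, , o] <- y[, , o] + b[o]
  y
}

refLRelu <- function(x) ifelse(x < 0, 0.01 * x, x)

# double-precision replica of the network forward pass for a tiny
# configuration, mirroring the layer topology of netForward
refNetForward <- function(model, x) {
  cfg <- model@config
  P <- model@params
  E <- cfg@nEchoes
  x <- x * cfg@inputScale
  if (cfg@variant != "no_rnn") {
    nl <- length(cfg@streamDepths)
    ord <- if (cfg@streamDirection == "forward") seq_len(E) else rev(seq_len(E))
    outs <- vector("list", E)
    hidden_prev <- NULL
    for (t in ord) {
      a <- x[, , t, drop = FALSE]
      hidden <- vector("list", nl)
      for (l in seq_len(nl)) {
        pre <- refConvFwd(a, P[[paste0("stream_w", l)]],
                          P[[paste0("stream_b", l)]], 1, 1)
        if (!is.null(hidden_prev))
          pre <- pre + cfg@lambdaW *
            refConvFwd(hidden_prev[[l]], P[[paste0("inter_w", l)]],
                       P[[paste0("inter_b", l)]], 1, 1)
        r <- refLRelu(pre)
        gl <- P[[paste0("gain", l)]][, t]
        a <- r * rep(gl, each = dim(r)[1] * dim(r)[2])
        hidden[[l]] <- a
      }
      outs[[t]] <- refConvFwd(hidden[[nl]], P[[paste0("stream_w", nl + 1)]],
                              P[[paste0("stream_b", nl + 1)]], 1, 1) +
        x[, , t, drop = FALSE]
      hidden_prev <- hidden
    }
    u <- array(0, c(dim(x)[1:2], E))
    for (t in seq_len(E)) u[, , t] <- outs[[t]][, , 1]
  } else u <- x
  enc <- cfg@encoderDepths
  acts <- vector("list", length(enc))
  a <- u
  for (k in seq_along(enc)) {
    a <- refLRelu(refConvFwd(a, P[[paste0("enc_w", k)]],
                             P[[paste0("enc_b", k)]], 2, 1))
    acts[[k]] <- a
  }
  skips <- c(rev(acts[-length(acts)]), list(u))
  tc <- cfg@decoderDepths$tconv
  for (k in seq_along(tc)) {
    tout <- refLRelu(refTConvFwd(a, P[[paste0("dec_t_w", k)]],
                                 P[[paste0("dec_t_b", k)]], 2, 1))
    cat_in <- if (is.null(skips[[k]])) tout else {
      d1 <- dim(tout); d2 <- dim(skips[[k]])
      arr <- array(0, c(d1[1], d1[2], d1[3] + d2[3]))
      arr[, , seq_len(d1[3])] <- tout
      arr[, , d1[3] + seq_len(d2[3])] <- skips[[k]]
      arr
    }
    a <- refLRelu(refConvFwd(cat_in, P[[paste0("dec_c_w", k)]],
                             P[[paste0("dec_c_b", k)]], 1, 1))
  }
  refConvFwd(a, P$head_w, P$head_b, 1, 1)[, , 1]
}

# a tiny network configuration exercising every layer type
tinyModelConfig <- function(variant = "full", n_echoes = 3L) {
  new("ModelConfig", variant = variant, nEchoes = as.integer(n_echoes),
      streamDepths = c(3L, 4L), encoderDepths = c(4L, 6L),
      decoderDepths = list(tconv = c(5L, 4L), conv = c(6L, 5L)),
      lambdaW = 0.2, streamDirection = "forward", inputScale = 1)
}

# brute-force masked GLCM: enumerate every pixel pair per offset
refGlcm <- function(map, roi, n_levels, t2_range) {
  m <- as.array(map); r <- as.array(roi) > 0
  if (length(dim(m)) == 2L) { dim(m) <- c(dim(m), 1L); dim(r) <- dim(m) }
  q <- pmin(pmax(m, t2_range[1]), t2_range[2])
  q <- pmin(floor((q - t2_range[1]) / diff(t2_range) * n_levels) + 1L, n_levels)
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  vals <- matrix(NA_real_, 4, length(offsets))
  for (oi in seq_along(offsets)) {
    o <- offsets[[oi]]
    cm <- matrix(0, n_levels, n_levels)
    for (z in seq_len(dim(q)[3]))
      for (i in seq_len(dim(q)[1])) for (j in seq_len(dim(q)[2])) {
        i2 <- i + o[1]; j2 <- j + o[2]
        if (i2 < 1 || i2 > dim(q)[1] || j2 < 1 || j2 > dim(q)[2]) next
        if (!r[i, j, z] || !r[i2, j2, z]) next
        a <- q[i, j, z]; b <- q[i2, j2, z]
        cm[a, b] <- cm[a, b] + 1
        cm[b, a] <- cm[b, a] + 1
      }
    if (sum(cm) == 0) next
    p <- cm / sum(cm)
    dij <- abs(outer(seq_len(n_levels), seq_len(n_levels), "-"))
    vals[, oi] <- c(sum(p * dij^2), sum(p * dij), sum(p / (1 + dij^2)),
                    sum(p^2))
  }
  out <- rowMeans(vals, na.rm = TRUE)
  out <- c(out, sqrt(out[4]))   # energy from the orientation-averaged ASM
  names(out) <- c("contrast", "dissimilarity", "homogeneity", "asm", "energy")
  out
}

# small knee phantom used across tests
testPhantom <- function(seed = 1L, noise = 0.02, lesions = 2L)
  generatePhantom(phantomConfig(grid = c(32L, 32L, 8L), noise_sigma = noise,
                                lesion_count = lesions, seed = seed))
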