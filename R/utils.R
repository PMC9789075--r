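#' @useDynLib AccelT2, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats fft quantile rnorm runif median sd cor.test pf qf var
#' @importFrom utils write.csv head
NULL

## Run expr with a private RNG stream, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a stage seed from a base seed, kept within 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + as.double(offset) * 12345L) %% 2147483629)
}

## Centre the DC component of a ky-kz matrix (and undo it).
fftshift2 <- function(m) {
  h <- floor(nrow(m) / 2); w <- floor(ncol(m) / 2)
  m[c(seq_len(nrow(m))[-seq_len(h)], seq_len(h)),
    c(seq_len(ncol(m))[-seq_len(w)], seq_len(w)), drop = FALSE]
}

ifftshift2 <- function(m) {
  h <- ceiling(nrow(m) / 2); w <- ceiling(ncol(m) / 2)
  m[c(seq_len(nrow(m))[-seq_len(h)], seq_len(h)),
    c(seq_len(ncol(m))[-seq_len(w)], seq_len(w)), drop = FALSE]
}

## Separable bilinear-interpolation matrix mapping a length-n axis onto
## length-m (rows sum to 1); resize is R %*% img %*% t(C).
resizeMatrix <- function(n, m) {
  out <- matrix(0, m, n)
  if (n == 1) { out[, 1] <- 1; return(out) }
  # align centres, torchvision-style (align_corners = FALSE)
  src <- ((seq_len(m) - 0.5) * n / m) - 0.5
  src <- pmin(pmax(src, 0), n - 1)
  lo <- floor(src); hi <- pmin(lo + 1, n - 1); frac <- src - lo
  for (i in seq_len(m)) {
    out[i, lo[i] + 1] <- out[i, lo[i] + 1] + (1 - frac[i])
    out[i, hi[i] + 1] <- out[i, hi[i] + 1] + frac[i]
  }
  out
}

## Rigid in-plane warp (rotation in degrees about image centre, then integer
## translation). method "bilinear" for images, "nearest" for label masks.
## Out-of-frame pixels are zero-filled.
warpImage <- function(img, dy = 0, dx = 0, angle = 0,
                      method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- matrix(seq_len(h), h, w) - cy
  gx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: output pixel -> source location
  sy <- cos(th) * gy + sin(th) * gx + cy - dy
  sx <- -sin(th) * gy + cos(th) * gx + cx - dx
  out <- matrix(0, h, w)
  if (method == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= h & rx >= 1 & rx <= w
    out[ok] <- img[cbind(ry[ok], rx[ok])]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    for (oy in 0:1) for (ox in 0:1) {
      yy <- y0 + oy; xx <- x0 + ox
      wgt <- (if (oy == 0) 1 - fy else fy) * (if (ox == 0) 1 - fx else fx)
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w & wgt > 0
      out[ok] <- out[ok] + wgt[ok] * img[cbind(yy[ok], xx[ok])]
    }
  }
  out
}
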