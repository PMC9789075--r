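#' Phantom configuration
#'
#' Builds the configuration for a synthetic multi-echo acquisition that
#' emulates the statistical structure of T2-prepared snapshot gradient-echo
#' data: thin high-T2 "cartilage" arcs (knee/hip) or elliptical "IVD"
#' regions (spine) embedded in a lower-T2 tissue background, imaged at the
#' anatomy's echo times and corrupted by Rician magnitude noise.
#'
#' Default tissue values place cartilage T2 (30-60 ms) and disc T2
#' (60-130 ms) in the transition band of the corresponding sigmoid loss
#' operator, with focal lesions of elevated T2 exercising local-pattern
#' retention.
#'
#' @param grid integer c(n_y, n_x, n_z) voxel grid. n_y and n_z are the
#'   phase-encode extents seen by the undersampler.
#' @param anatomy "knee", "hip" or "spine".
#' @param echo_times echo times in ms; defaults to the anatomy preset.
#' @param t2_background,t2_roi,pd_background,pd_roi tissue value ranges;
#'   class values are drawn uniformly from these per phantom.
#' @param lesion_count number of focal high-T2 lesions inside the ROI.
#' @param lesion_t2_delta T2 elevation of lesions (ms).
#' @param noise_sigma Rician noise level as a fraction of peak proton
#'   density.
#' @param seed integer RNG seed; the phantom is bit-reproducible from it.
#' @return a list of class "phantomConfig".
#' @export
phantomConfig <- function(grid = c(32L, 32L, 8L),
                          anatomy = c("knee", "hip", "spine"),
                          echo_times = NULL,
                          t2_background = NULL, t2_roi = NULL,
                          pd_background = c(200, 350),
                          pd_roi = c(350, 500),
                          lesion_count = 2L, lesion_t2_delta = 15,
                          noise_sigma = 0.02, seed = 1L) {
  anatomy <- match.arg(anatomy)
  preset <- anatomyPreset(anatomy)
  if (is.null(echo_times)) echo_times <- preset@echoTimes
  if (is.null(t2_background))
    t2_background <- switch(anatomy, knee = c(20, 20), hip = c(15, 15),
                            spine = c(40, 40))
  if (is.null(t2_roi))
    t2_roi <- switch(anatomy, knee = c(30, 60), hip = c(25, 55),
                     spine = c(60, 130))
  if (length(echo_times) < 2 || echo_times[1] != 0 ||
      any(diff(echo_times) <= 0))
    stop("echo_times must be strictly increasing and start at 0 ms")
  if (any(c(t2_background, t2_roi) <= 0)) stop("T2 ranges must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 1L)) stop("grid must be (n_y, n_x, n_z)")
  structure(list(grid = grid, anatomy = anatomy, echo_times = echo_times,
                 t2_background = t2_background, t2_roi = t2_roi,
                 pd_background = pd_background, pd_roi = pd_roi,
                 lesion_count = as.integer(lesion_count),
                 lesion_t2_delta = lesion_t2_delta,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantomConfig")
}

## In-plane geometry helpers -------------------------------------------------

## A curved cartilage-like band: voxels within [r, r + thickness] of a
## centre, restricted to an angular sector, split into two compartments.
arcRoi <- function(ny, nx) {
  r0 <- runif(1, 0.22, 0.32) * min(ny, nx)
  th <- runif(1, 2, 6)
  ang0 <- runif(1, 0, 2 * pi)
  span <- runif(1, pi * 0.6, pi * 1.2)
  cy <- ny / 2 + runif(1, -1.5, 1.5)
  cx <- nx / 2 + runif(1, -1.5, 1.5)
  gy <- matrix(seq_len(ny), ny, nx) - cy
  gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  rad <- sqrt(gy^2 + gx^2)
  ang <- (atan2(gx, gy) - ang0) %% (2 * pi)
  inarc <- rad >= r0 & rad <= r0 + th & ang <= span
  lab <- matrix(0L, ny, nx)
  lab[inarc & ang <= span / 2] <- 1L
  lab[inarc & ang > span / 2] <- 2L
  lab
}

## Stacked elliptical disc-like regions for the spine preset.
discRoi <- function(ny, nx) {
  lab <- matrix(0L, ny, nx)
  n_disc <- if (ny >= 28) 3L else 2L
  centres <- seq(0.25, 0.75, length.out = n_disc) * ny +
    runif(n_disc, -1, 1)
  cx <- nx / 2 + runif(1, -2, 2)
  a <- runif(n_disc, 1.6, 2.6)           # semi-axis along y
  b <- runif(n_disc, 3.5, 6)             # semi-axis along x
  gy <- matrix(seq_len(ny), ny, nx)
  gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (k in seq_len(n_disc)) {
    inside <- ((gy - centres[k]) / a[k])^2 + ((gx - cx) / b[k])^2 <= 1
    lab[inside] <- k
  }
  lab
}

#' Generate a synthetic phantom acquisition
#'
#' Draws ROI geometry and tissue class values from the configured ranges,
#' builds ground-truth T2 and proton-density maps, and simulates the
#' multi-echo magnitude images with \code{\link{simulateEchoes}}. With
#' \code{noise_sigma = 0} and \code{lesion_count = 0} every ROI voxel's T2
#' equals its compartment's class value exactly.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return a \linkS4class{PhantomTruth}.
#' @export
generatePhantom <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  g <- config$grid; ny <- g[1]; nx <- g[2]; nz <- g[3]
  if (ny < 16L || nx < 16L)
    stop("grid too small to place a tissue ROI: need at least 16 x 16 in-plane")
  withSeed(config$seed, {
    lab2d <- if (config$anatomy == "spine") discRoi(ny, nx) else arcRoi(ny, nx)
    if (sum(lab2d > 0) < 8L)
      stop("grid too small to place a tissue ROI of usable size")
    # tissue body: inscribed ellipse covering most of the plane
    gy <- matrix(seq_len(ny), ny, nx); gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    body2d <- ((gy - (ny + 1) / 2) / (0.47 * ny))^2 +
      ((gx - (nx + 1) / 2) / (0.47 * nx))^2 <= 1
    lab2d[!body2d] <- 0L

    # ROI occupies the central slices; background tissue all slices
    zroi <- if (nz >= 4) seq.int(max(2L, floor(nz / 4) + 1L),
                                 min(nz - 1L, nz - floor(nz / 4))) else seq_len(nz)
    labels <- array(0L, g); body <- array(FALSE, g)
    for (z in seq_len(nz)) {
      body[, , z] <- body2d
      if (z %in% zroi) labels[, , z] <- lab2d
    }

    ncomp <- max(lab2d)
    t2_bg <- runif(1, config$t2_background[1], config$t2_background[2])
    t2_cls <- runif(ncomp, config$t2_roi[1], config$t2_roi[2])
    pd_bg <- runif(1, config$pd_background[1], config$pd_background[2])
    pd_cls <- runif(ncomp, config$pd_roi[1], config$pd_roi[2])

    t2 <- array(NA_real_, g); pd <- array(0, g)
    t2[body] <- t2_bg; pd[body] <- pd_bg
    for (k in seq_len(ncomp)) {
      t2[labels == k] <- t2_cls[k]
      pd[labels == k] <- pd_cls[k]
    }

    # focal lesions: small disks of elevated T2 inside the ROI
    if (config$lesion_count > 0) {
      roi_idx <- which(lab2d > 0, arr.ind = TRUE)
      for (l in seq_len(config$lesion_count)) {
        c_yx <- roi_idx[sample.int(nrow(roi_idx), 1L), ]
        rad <- runif(1, 1, 2)
        les2d <- (gy - c_yx[1])^2 + (gx - c_yx[2])^2 <= rad^2
        les2d <- les2d & lab2d > 0
        for (z in zroi)
          t2[, , z][les2d] <- t2[, , z][les2d] + config$lesion_t2_delta
      }
    }

    echo_seed <- deriveSeed(config$seed, 7L)
    echoes <- simulateEchoes(t2, pd, config$echo_times,
                             noise_sigma = config$noise_sigma,
                             seed = echo_seed)
    new("PhantomTruth", t2 = t2, pd = pd,
        roi = new("RoiMask", labels = labels),
        echoes = echoes, config = unclass(config))
  })
}

#' Simulate multi-echo magnitude images from truth maps
#'
#' Evaluates the mono-exponential signal model S(TE) = PD * exp(-TE / T2)
#' voxel-wise and, for \code{noise_sigma > 0}, applies Rician noise: two
#' independent Gaussian channels of standard deviation
#' \code{noise_sigma * max(pd)} added in quadrature to the magnitude.
#'
#' @param t2_true,pd_true numeric arrays of matching shape; T2 in ms (NA
#'   allowed where \code{pd_true} is 0).
#' @param echo_times echo times in ms, first must be 0.
#' @param noise_sigma noise standard deviation as a fraction of peak PD.
#' @param seed RNG seed for the noise draw.
#' @return an \linkS4class{EchoSeries}.
#' @export
simulateEchoes <- function(t2_true, pd_true, echo_times, noise_sigma = 0,
                           seed = 1L) {
  if (!identical(dim(t2_true), dim(pd_true)))
    stop("t2_true and pd_true must have identical dimensions")
  if (length(echo_times) < 1 || echo_times[1] != 0)
    stop("echo_times must start at 0 ms")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  d <- dim(pd_true)
  if (length(d) == 2L) { dim(t2_true) <- c(d, 1L); dim(pd_true) <- c(d, 1L); d <- c(d, 1L) }
  ne <- length(echo_times)
  out <- array(0, c(d, ne))
  decay <- array(0, d)
  tissue <- pd_true > 0
  withSeed(seed, {
    sig <- noise_sigma * max(pd_true)
    for (e in seq_len(ne)) {
      decay[] <- 0
      decay[tissue] <- pd_true[tissue] * exp(-echo_times[e] / t2_true[tissue])
      if (sig > 0) {
        n1 <- array(rnorm(length(decay), sd = sig), d)
        n2 <- array(rnorm(length(decay), sd = sig), d)
        decay <- sqrt((decay + n1)^2 + n2^2)
      }
      out[, , , e] <- decay
    }
  })
  new("EchoSeries", data = out, echoTimes = as.numeric(echo_times))
}
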