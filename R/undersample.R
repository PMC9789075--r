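#' Sampling plan for retrospective acceleration
#'
#' Describes the target undersampling of the ky-kz phase-encode plane:
#' acquisition restricted to a centred ellipse (corner k-space never
#' acquired), a fully-sampled central region, and a center-weighted
#' variable-density Poisson-disc pattern calibrated to the acceleration
#' factor R. R is defined relative to ellipse-interior points; the central
#' region counts toward the sampled points.
#'
#' @param R target acceleration factor (>= 1).
#' @param grid integer c(n_ky, n_kz).
#' @param n_echoes number of echo images; each gets a unique pattern.
#' @param ellipse_area_fraction ellipse area / rectangle area (default 0.7).
#' @param central_square_area_fraction area fraction of the fully sampled
#'   central region (default 0.05).
#' @param seed integer RNG seed.
#' @param calibration_tolerance relative tolerance on realised R.
#' @param alpha growth rate of the exclusion radius with normalised
#'   elliptical radius: r(d) = r0 * (1 + alpha * d).
#' @return a \linkS4class{SamplingPlan}.
#' @export
samplingPlan <- function(R, grid, n_echoes = 4L,
                         ellipse_area_fraction = 0.7,
                         central_square_area_fraction = 0.05,
                         seed = 1L, calibration_tolerance = 0.02,
                         alpha = 2.0) {
  new("SamplingPlan", R = R, ellipseAreaFraction = ellipse_area_fraction,
      centralSquareAreaFraction = central_square_area_fraction,
      grid = as.integer(grid), nEchoes = as.integer(n_echoes),
      seed = as.integer(seed), calibrationTolerance = calibration_tolerance,
      alpha = alpha)
}

## Normalised elliptical coordinates of every grid point relative to the
## support semi-axes (DC at the grid centre, fftshift convention).
ellipseCoords <- function(n_ky, n_kz, rel_a, rel_b) {
  cy <- floor(n_ky / 2) + 1L
  cz <- floor(n_kz / 2) + 1L
  u <- (seq_len(n_ky) - cy) / (n_ky / 2)
  v <- (seq_len(n_kz) - cz) / (n_kz / 2)
  outer(u / rel_a, v / rel_b, function(a, b) sqrt(a^2 + b^2))
}

#' Elliptical acquisition support
#'
#' Boolean mask of the centred, axis-aligned ellipse in ky-kz whose discrete
#' area is the requested fraction of the rectangular grid (within +/- 0.01).
#' Semi-axes start at the continuous solution sqrt(fraction / (pi/4)) of
#' each half-extent and are adjusted discretely.
#'
#' @param n_ky,n_kz grid extents (>= 4).
#' @param ellipse_area_fraction target area fraction in (0, 1]; 1 selects
#'   the full rectangle.
#' @return logical matrix (n_ky x n_kz).
#' @export
ellipticalSupport <- function(n_ky, n_kz, ellipse_area_fraction = 0.7) {
  stopifnot(n_ky >= 4, n_kz >= 4)
  f <- ellipse_area_fraction
  if (f <= 0 || f > 1) stop("ellipse_area_fraction must be in (0, 1]")
  if (f == 1) return(matrix(TRUE, n_ky, n_kz))
  n <- n_ky * n_kz
  rel <- sqrt(f / (pi / 4))
  # discrete adjustment: scale both semi-axes by s until the pixel count
  # matches the requested fraction
  areaAt <- function(s) sum(ellipseCoords(n_ky, n_kz, rel * s, rel * s) <= 1) / n
  lo <- 0.7; hi <- 1.3
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (areaAt(mid) < f) lo <- mid else hi <- mid
  }
  best <- NULL; besterr <- Inf
  for (s in seq(lo - 0.02, hi + 0.02, length.out = 81)) {
    err <- abs(areaAt(s) - f)
    if (err < besterr) { besterr <- err; best <- s }
  }
  if (besterr > 0.01)
    stop(sprintf(
      "requested ellipse fraction %.3f unreachable on a %d x %d grid; closest achievable is %.3f",
      f, n_ky, n_kz, areaAt(best)))
  ellipseCoords(n_ky, n_kz, rel * best, rel * best) <= 1
}

## Fully-sampled central region: a rectangle with the grid's aspect ratio
## occupying `frac` of the grid area, odd side lengths for symmetry about DC.
centralRegion <- function(n_ky, n_kz, frac) {
  side <- function(n) {
    s <- max(1L, round(sqrt(frac) * n))
    if (s %% 2L == 0L) s <- s + 1L
    min(s, n)
  }
  sy <- side(n_ky); sz <- side(n_kz)
  cy <- floor(n_ky / 2) + 1L; cz <- floor(n_kz / 2) + 1L
  out <- matrix(FALSE, n_ky, n_kz)
  out[cy + seq(-(sy - 1L) / 2L, (sy - 1L) / 2L),
      cz + seq(-(sz - 1L) / 2L, (sz - 1L) / 2L)] <- TRUE
  out
}

## Greedy dart-throwing variable-density Poisson disc at exclusion radius
## r(d) = r0 (1 + alpha d), with the central region pre-accepted and a fixed
## candidate order so that calibration over r0 is stable.
throwDarts <- function(cand_yx, cand_d, acc_yx, r0, alpha) {
  acc_y <- acc_yx[, 1]; acc_z <- acc_yx[, 2]
  keep <- logical(nrow(cand_yx))
  for (i in seq_len(nrow(cand_yx))) {
    r2 <- (r0 * (1 + alpha * cand_d[i]))^2
    dy <- acc_y - cand_yx[i, 1]; dz <- acc_z - cand_yx[i, 2]
    if (!any(dy * dy + dz * dz < r2)) {
      keep[i] <- TRUE
      acc_y <- c(acc_y, cand_yx[i, 1]); acc_z <- c(acc_z, cand_yx[i, 2])
    }
  }
  keep
}

#' Center-weighted Poisson-disc sampling mask for one echo
#'
#' Dart-throwing Poisson disc restricted to the elliptical support, with
#' exclusion radius growing linearly with normalised elliptical radius
#' (center-weighted density), the central region fully sampled, and the
#' base radius r0 calibrated by bisection so that (ellipse points) /
#' (sampled points) matches the plan's R within its tolerance. Each echo
#' index derives its own RNG stream from the plan seed, so patterns are
#' unique per echo yet bit-reproducible.
#'
#' @param plan a \linkS4class{SamplingPlan}.
#' @param echo_index 1-based echo number.
#' @param support optional precomputed elliptical support mask.
#' @return logical matrix (n_ky x n_kz) with attribute "realizedR".
#' @export
poissonMask <- function(plan, echo_index = 1L, support = NULL) {
  n_ky <- plan@grid[1]; n_kz <- plan@grid[2]
  if (is.null(support))
    support <- ellipticalSupport(n_ky, n_kz, plan@ellipseAreaFraction)
  n_ell <- sum(support)
  if (plan@R == 1) {
    out <- support
    attr(out, "realizedR") <- 1
    return(out)
  }
  target <- n_ell / plan@R
  central <- centralRegion(n_ky, n_kz, plan@centralSquareAreaFraction) & support
  if (sum(central) > target * (1 + plan@calibrationTolerance))
    stop(sprintf(
      "central region (%d points) alone exceeds the sampling budget for R = %g (achievable R <= %.2f)",
      sum(central), plan@R, n_ell / sum(central)))

  rel <- sqrt(plan@ellipseAreaFraction / (pi / 4))
  dmat <- ellipseCoords(n_ky, n_kz, rel, rel)
  # re-normalise distances to the realised support boundary
  dmat <- dmat / max(dmat[support])

  cand_idx <- which(support & !central, arr.ind = TRUE)
  withSeed(deriveSeed(plan@seed, echo_index), {
    ord <- sample.int(nrow(cand_idx))
  })
  cand_idx <- cand_idx[ord, , drop = FALSE]
  cand_d <- dmat[cand_idx]
  acc0 <- which(central, arr.ind = TRUE)

  countAt <- function(r0)
    sum(throwDarts(cand_idx, cand_d, acc0, r0, plan@alpha)) + nrow(acc0)
  lo <- 1e-3; hi <- max(n_ky, n_kz)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (countAt(mid) > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  best_r0 <- NULL; besterr <- Inf
  for (r0 in unique(c((lo + hi) / 2, seq(lo * 0.9, hi * 1.1, length.out = 25)))) {
    err <- abs(countAt(r0) - target) / target
    if (err < besterr) { besterr <- err; best_r0 <- r0 }
    if (err <= plan@calibrationTolerance && r0 == (lo + hi) / 2) break
  }
  keep <- throwDarts(cand_idx, cand_d, acc0, best_r0, plan@alpha)
  out <- central
  out[cand_idx[keep, , drop = FALSE]] <- TRUE

  # Dart-throwing counts move in discrete jumps, so on coarse grids the
  # bisection can straddle the integer budget. Correct by adding the
  # candidate farthest from all accepted points (or removing the most
  # crowded non-central point), which preserves the blue-noise character.
  target_n <- max(round(target), sum(central))
  minDistTo <- function(pts, ref) {
    vapply(seq_len(nrow(pts)), function(i)
      min((ref[, 1] - pts[i, 1])^2 + (ref[, 2] - pts[i, 2])^2), numeric(1))
  }
  while (sum(out) < target_n) {
    acc <- which(out, arr.ind = TRUE)
    free <- which(support & !out, arr.ind = TRUE)
    if (!nrow(free)) break
    dmin <- minDistTo(free, acc)
    out[free[which.max(dmin), , drop = FALSE]] <- TRUE
  }
  while (sum(out) > target_n) {
    acc <- which(out & !central, arr.ind = TRUE)
    if (!nrow(acc)) break
    all_acc <- which(out, arr.ind = TRUE)
    dmin <- vapply(seq_len(nrow(acc)), function(i) {
      d2 <- (all_acc[, 1] - acc[i, 1])^2 + (all_acc[, 2] - acc[i, 2])^2
      min(d2[d2 > 0])
    }, numeric(1))
    out[acc[which.min(dmin), , drop = FALSE]] <- FALSE
  }
  realized <- n_ell / sum(out)
  if (abs(realized - plan@R) / plan@R > plan@calibrationTolerance)
    stop(sprintf(
      "Poisson-disc calibration failed for R = %g: best achieved R = %.3f (tolerance %.3g)",
      plan@R, realized, plan@calibrationTolerance))
  attr(out, "realizedR") <- realized
  out
}

#' Realise the full set of per-echo sampling masks for a plan
#'
#' @param plan a \linkS4class{SamplingPlan}.
#' @return a \linkS4class{SamplingMask}.
#' @export
buildSamplingMask <- function(plan) {
  support <- ellipticalSupport(plan@grid[1], plan@grid[2],
                               plan@ellipseAreaFraction)
  masks <- array(FALSE, c(plan@grid, plan@nEchoes))
  rr <- numeric(plan@nEchoes)
  for (e in seq_len(plan@nEchoes)) {
    m <- poissonMask(plan, e, support)
    rr[e] <- attr(m, "realizedR")
    masks[, , e] <- m
  }
  new("SamplingMask", masks = masks, support = support, realizedR = rr,
      plan = plan)
}

## For each echo, index of the sampled echo whose line initialises each
## ky-kz position (0 = sampled nowhere, zero-filled). Temporally closest
## donor wins; ties go to the earlier echo.
donorIndex <- function(masks, echo_times) {
  ne <- dim(masks)[3]
  out <- vector("list", ne)
  for (e in seq_len(ne)) {
    ord <- order(abs(echo_times - echo_times[e]), seq_len(ne))
    donor <- matrix(0L, dim(masks)[1], dim(masks)[2])
    for (d in ord) {
      unset <- donor == 0L & masks[, , d]
      donor[unset] <- d
    }
    out[[e]] <- donor
  }
  out
}

#' Share k-space lines between echoes
#'
#' For every ky-kz line and echo: keep the line's own data if sampled at
#' that echo; otherwise copy the line from the sampled echo with the
#' temporally closest echo time (ties resolved toward the earlier echo,
#' which carries more signal); lines sampled at no echo are zero-filled.
#'
#' @param kspaces list of complex ky-kz matrices, one per echo.
#' @param masks logical array (ky, kz, echo) of sampling patterns.
#' @param echo_times echo times (ms), sorted ascending.
#' @return list of filled complex matrices.
#' @export
shareEchoLines <- function(kspaces, masks, echo_times) {
  ne <- length(kspaces)
  if (dim(masks)[3] != ne || length(echo_times) != ne)
    stop("need one mask and one echo time per k-space")
  d <- dim(kspaces[[1]])
  for (k in kspaces) if (!identical(dim(k), d))
    stop("k-space matrices must share dimensions")
  if (!identical(dim(masks)[1:2], d))
    stop("mask grid does not match the k-space grid")
  donors <- donorIndex(masks, echo_times)
  out <- vector("list", ne)
  for (e in seq_len(ne)) {
    filled <- matrix(0 + 0i, d[1], d[2])
    for (src in seq_len(ne)) {
      take <- donors[[e]] == src
      filled[take] <- kspaces[[src]][take]
    }
    out[[e]] <- filled
  }
  out
}

#' Retrospectively undersample a multi-echo volume
#'
#' Fourier transforms each echo volume along the two phase-encode axes
#' (readout fully sampled), applies the per-echo Poisson-disc masks with
#' temporally-closest-echo line sharing and zero-filling, and inverse
#' transforms, returning the aliased magnitude images.
#'
#' @param echo_series an \linkS4class{EchoSeries}; its (y, z) extents must
#'   match the plan grid.
#' @param plan a \linkS4class{SamplingPlan}, or a prebuilt
#'   \linkS4class{SamplingMask}.
#' @return list with elements \code{echoes} (aliased
#'   \linkS4class{EchoSeries}) and \code{mask} (\linkS4class{SamplingMask}).
#' @export
undersampleVolume <- function(echo_series, plan) {
  stopifnot(is(echo_series, "EchoSeries"))
  mask <- if (is(plan, "SamplingMask")) plan else buildSamplingMask(plan)
  d <- dim(echo_series@data)
  if (!identical(as.integer(d[c(1, 3)]), mask@plan@grid))
    stop(sprintf("plan grid (%d x %d) does not match volume phase-encode grid (%d x %d)",
                 mask@plan@grid[1], mask@plan@grid[2], d[1], d[3]))
  ne <- d[4]
  if (dim(mask@masks)[3] != ne)
    stop("number of masks does not match number of echoes")
  te <- echo_series@echoTimes
  donors <- donorIndex(mask@masks, te)

  # forward FFT per echo, per readout position: (y, z) plane, DC centred
  ks <- vector("list", ne)
  for (e in seq_len(ne)) {
    K <- array(0 + 0i, d[c(1, 3, 2)])
    for (x in seq_len(d[2]))
      K[, , x] <- fftshift2(fft(echo_series@data[, x, , e]))
    ks[[e]] <- K
  }
  out <- array(0, d)
  npts <- d[1] * d[3]
  for (e in seq_len(ne)) {
    filled <- array(0 + 0i, d[c(1, 3, 2)])
    for (src in seq_len(ne)) {
      take <- donors[[e]] == src
      if (!any(take)) next
      idx <- which(take)
      for (x in seq_len(d[2]))
        filled[, , x][idx] <- ks[[src]][, , x][idx]
    }
    for (x in seq_len(d[2]))
      out[, x, , e] <- Mod(fft(ifftshift2(filled[, , x]), inverse = TRUE)) / npts
  }
  list(echoes = new("EchoSeries", data = out, echoTimes = te), mask = mask)
}
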