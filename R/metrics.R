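#' ROI-restricted normalised root-mean-square error
#'
#' NRMSE = ||T2 - T2_hat||_2 over the tissue of interest, divided by
#' ||T2||_2 over the same pixels. Scale-equivariant: scaling both maps by
#' a positive constant leaves it unchanged.
#'
#' @param t2_true,t2_pred T2 maps (ms), identical shape.
#' @param roi logical or integer mask; positive/TRUE marks the tissue.
#' @return NRMSE as a fraction (multiply by 100 for percent).
#' @export
roiNrmse <- function(t2_true, t2_pred, roi) {
  sel <- roi > 0
  if (!any(sel)) stop("empty ROI")
  tt <- t2_true[sel]; tp <- t2_pred[sel]
  denom <- sqrt(sum(tt^2))
  if (denom == 0) stop("ROI truth norm is zero; NRMSE undefined")
  sqrt(sum((tt - tp)^2)) / denom
}

#' T2-value equivalent of an error rate
#'
#' Converts an NRMSE fraction into milliseconds by multiplying with the
#' mean ground-truth T2 in the tissue of interest.
#'
#' @param nrmse error fraction from \code{\link{roiNrmse}}.
#' @param t2_true ground-truth map (ms).
#' @param roi tissue mask.
#' @return error in ms.
#' @export
t2Equivalent <- function(nrmse, t2_true, roi) {
  sel <- roi > 0
  if (!any(sel)) stop("empty ROI")
  nrmse * mean(t2_true[sel])
}

#' Bland-Altman agreement analysis
#'
#' Bias and limits of agreement between paired compartment-mean T2
#' values. Differences are predicted minus true; the limits of agreement
#' are bias +/- 1.96 standard deviations of the differences.
#'
#' @param true_means,pred_means paired numeric vectors (>= 2 pairs).
#' @return list with \code{bias}, \code{loa} (lower, upper), \code{sd}
#'   and a \code{points} data.frame (mean, difference).
#' @export
blandAltman <- function(true_means, pred_means) {
  if (length(true_means) != length(pred_means))
    stop("paired vectors must have equal length")
  if (length(true_means) < 2) stop("need at least 2 pairs")
  diffs <- pred_means - true_means
  bias <- mean(diffs); s <- sd(diffs)
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s), sd = s,
       points = data.frame(mean = (true_means + pred_means) / 2,
                           difference = diffs))
}

#' Voxel-wise Pearson correlation in the tissue of interest
#'
#' @param t2_true,t2_pred T2 maps, identical shape.
#' @param roi tissue mask with at least 3 marked pixels.
#' @return list with \code{r} and two-sided \code{p}.
#' @export
pearsonRoi <- function(t2_true, t2_pred, roi) {
  sel <- roi > 0
  if (sum(sel) < 3) stop("need at least 3 ROI pixels")
  x <- t2_true[sel]; y <- t2_pred[sel]
  if (var(x) == 0 || var(y) == 0)
    stop("degenerate variance: Pearson correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Masked GLCM texture metrics
#'
#' Gray-level co-occurrence metrics of a T2 map restricted to a tissue
#' mask. The map is clipped to \code{t2_range} and uniformly quantised to
#' \code{n_levels} gray levels; symmetric co-occurrence counts are
#' accumulated over pixel pairs whose both members lie in the ROI, at
#' offset distance 1 pixel and orientations 0, 45, 90 and 135 degrees.
#' For 3-D input, counts are pooled across slices before normalisation.
#' Each metric is computed per orientation from the normalised matrix and
#' averaged over the four orientations:
#' contrast = sum p (i - j)^2, dissimilarity = sum p |i - j|,
#' homogeneity = sum p / (1 + (i - j)^2), ASM = sum p^2; energy is the
#' square root of the orientation-averaged ASM, so ASM = energy^2 holds
#' for every report.
#'
#' @param t2_map 2-D or 3-D T2 map (ms).
#' @param roi mask of the same shape.
#' @param n_levels number of gray levels (default 32).
#' @param t2_range clipping range in ms before quantisation.
#' @return named numeric vector (contrast, dissimilarity, homogeneity,
#'   asm, energy).
#' @export
glcmMetrics <- function(t2_map, roi, n_levels = 32L, t2_range = c(0, 150)) {
  m <- as.array(t2_map); r <- as.array(roi) > 0
  if (!identical(dim(m), dim(r))) stop("map/mask shape mismatch")
  if (length(dim(m)) == 2L) { dim(m) <- c(dim(m), 1L); dim(r) <- dim(m) }
  m[is.na(m)] <- t2_range[1]
  q <- pmin(pmax(m, t2_range[1]), t2_range[2])
  q <- pmin(floor((q - t2_range[1]) / diff(t2_range) * n_levels) + 1L,
            n_levels)
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  d <- dim(q)
  counts <- lapply(offsets, function(o) matrix(0, n_levels, n_levels))
  for (z in seq_len(d[3])) {
    qz <- q[, , z]; rz <- r[, , z]
    for (oi in seq_along(offsets)) {
      o <- offsets[[oi]]
      ys <- seq_len(d[1]); xs <- seq_len(d[2])
      y1 <- ys[ys + o[1] >= 1 & ys + o[1] <= d[1]]
      x1 <- xs[xs + o[2] >= 1 & xs + o[2] <= d[2]]
      if (!length(y1) || !length(x1)) next
      a <- qz[y1, x1, drop = FALSE]
      b <- qz[y1 + o[1], x1 + o[2], drop = FALSE]
      ok <- rz[y1, x1, drop = FALSE] & rz[y1 + o[1], x1 + o[2], drop = FALSE]
      if (!any(ok)) next
      tab <- table(factor(a[ok], levels = seq_len(n_levels)),
                   factor(b[ok], levels = seq_len(n_levels)))
      counts[[oi]] <- counts[[oi]] + tab + t(tab)   # symmetric counts
    }
  }
  if (all(vapply(counts, sum, numeric(1)) == 0))
    stop("no in-ROI neighbour pairs at any offset")
  lv <- seq_len(n_levels)
  dij <- abs(outer(lv, lv, "-"))
  per <- vapply(counts, function(cm) {
    s <- sum(cm)
    if (s == 0) return(rep(NA_real_, 4))
    p <- cm / s
    c(contrast = sum(p * dij^2), dissimilarity = sum(p * dij),
      homogeneity = sum(p / (1 + dij^2)), asm = sum(p^2))
  }, numeric(4))
  out <- rowMeans(per, na.rm = TRUE)
  # energy is defined on the orientation-averaged ASM so that
  # ASM = energy^2 holds for every report
  out <- c(out, sqrt(out[4]))
  names(out) <- c("contrast", "dissimilarity", "homogeneity", "asm",
                  "energy")
  out
}

#' Intraclass correlation coefficient, two-way model, single rater
#'
#' Agreement between a metric computed on ground-truth maps and the same
#' metric computed on predicted maps, across scans. The default is the
#' consistency form ICC(3,1) for a two-way mixed-effects, single-rater
#' design: (MS_R - MS_E) / (MS_R + (k - 1) MS_E) with k = 2 measurements
#' per scan; \code{type = "agreement"} uses the absolute-agreement form
#' that also charges the measurement-mean difference. The 95\% confidence
#' interval and p-value follow the F-distribution formulation of the
#' standard reporting guideline.
#'
#' @param x,y metric per scan from truth and prediction (length >= 3).
#' @param type "consistency" (default) or "agreement".
#' @param conf confidence level (default 0.95).
#' @return list with \code{icc}, \code{ci} (lower, upper), \code{p}.
#' @export
iccSingleRater <- function(x, y, type = c("consistency", "agreement"),
                           conf = 0.95) {
  type <- match.arg(type)
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3) stop("need at least 3 scans")
  k <- 2
  dat <- cbind(x, y)
  if (var(rowMeans(dat)) == 0)
    stop("zero between-scan variance: ICC undefined")
  grand <- mean(dat)
  rowm <- rowMeans(dat); colm <- colMeans(dat)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fv <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fv / qf(1 - alpha / 2, df1, df2)
    fu <- fv * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- pf(fv, df1, df2, lower.tail = FALSE)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    # Satterthwaite CI for ICC(A,1)
    a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fv <- msr / (a * msc + b * mse)
    fstar <- msr / mse
    df1 <- n - 1
    fl <- qf(1 - alpha / 2, df1, v); fu <- qf(1 - alpha / 2, v, df1)
    ci <- c(n * (msr - fl * mse) /
              (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
            n * (fu * msr - mse) /
              (k * msc + (k * n - k - n) * mse + n * fu * msr))
    p <- pf(fstar, df1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(icc = unname(icc), ci = ci, p = unname(p))
}

#' Per-compartment metric report for one scan
#'
#' Computes NRMSE, its T2-value equivalent, Pearson r and the mean true
#' and predicted T2 per ROI compartment.
#'
#' @param t2_true,t2_pred T2 maps.
#' @param roi integer compartment labels.
#' @return data.frame with one row per compartment.
#' @export
metricReport <- function(t2_true, t2_pred, roi) {
  labs <- sort(setdiff(unique(as.vector(roi)), 0))
  do.call(rbind, lapply(labs, function(l) {
    sel <- roi == l
    nr <- roiNrmse(t2_true, t2_pred, sel)
    pe <- tryCatch(pearsonRoi(t2_true, t2_pred, sel),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(compartment = l, nrmse = nr,
               t2_equiv = t2Equivalent(nr, t2_true, sel),
               pearson_r = pe$r, pearson_p = pe$p,
               mean_t2_true = mean(t2_true[sel]),
               mean_t2_pred = mean(t2_pred[sel]))
  }))
}
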