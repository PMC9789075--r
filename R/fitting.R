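#' Options for mono-exponential T2 fitting
#'
#' @param t2_bounds lower/upper T2 bounds in ms; degenerate or
#'   non-decaying voxels are clamped to the bounds and flagged.
#' @param signal_floor voxels whose TE = 0 signal does not exceed this are
#'   marked invalid (background air).
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param convergence_tolerance relative decrease of the residual
#'   sum-of-squares below which iteration stops.
#' @return a list of class "fitOptions".
#' @export
fitOptions <- function(t2_bounds = c(1, 300), signal_floor = 1e-6,
                       max_iterations = 30L, convergence_tolerance = 1e-10) {
  stopifnot(length(t2_bounds) == 2, all(t2_bounds > 0),
            t2_bounds[1] < t2_bounds[2])
  structure(list(t2_bounds = t2_bounds, signal_floor = signal_floor,
                 max_iterations = as.integer(max_iterations),
                 convergence_tolerance = convergence_tolerance),
            class = "fitOptions")
}

#' Fit a T2 map by per-voxel Levenberg-Marquardt
#'
#' Fits S(TE) = A * exp(-TE / T2) to every voxel of a multi-echo magnitude
#' series. All voxels are fitted simultaneously with vectorised damped
#' Gauss-Newton (Levenberg-Marquardt) steps, initialised from the
#' log-linear least-squares line through (TE, log S) over above-floor
#' echoes. Voxels whose TE = 0 signal is at or below the floor are invalid;
#' non-decaying voxels clamp to the upper T2 bound and are flagged.
#'
#' The fit is plain least squares on magnitudes; the Rician noise floor is
#' not modelled, matching standard practice for ground-truth map
#' generation.
#'
#' @param echo_series an \linkS4class{EchoSeries} with at least 3 echoes.
#' @param options a \code{\link{fitOptions}} list.
#' @return a \linkS4class{T2Map}.
#' @export
fitT2 <- function(echo_series, options = fitOptions()) {
  stopifnot(is(echo_series, "EchoSeries"))
  te <- echo_series@echoTimes
  if (length(te) < 3) stop("T2 fitting requires at least 3 echoes")
  d <- dim(echo_series@data)
  np <- prod(d[1:3]); ne <- d[4]
  S <- matrix(echo_series@data, np, ne)
  lb <- options$t2_bounds[1]; ub <- options$t2_bounds[2]

  valid <- S[, 1] > options$signal_floor
  idx <- which(valid)
  t2 <- rep(NA_real_, np); amp <- rep(NA_real_, np)
  bound <- rep(FALSE, np)

  if (length(idx)) {
    Sv <- S[idx, , drop = FALSE]
    # log-linear initialisation over echoes above the floor
    logS <- log(pmax(Sv, .Machine$double.eps))
    w <- (Sv > options$signal_floor) * 1
    sw <- rowSums(w)
    mx <- rowSums(w * rep(te, each = nrow(Sv))) / sw
    my <- rowSums(w * logS) / sw
    sxx <- rowSums(w * (rep(te, each = nrow(Sv)) - mx)^2)
    sxy <- rowSums(w * (rep(te, each = nrow(Sv)) - mx) * (logS - my))
    slope <- ifelse(sxx > 0, sxy / sxx, 0)
    T2 <- ifelse(slope < 0, -1 / slope, ub)
    T2 <- pmin(pmax(T2, lb), ub)
    A <- exp(my - slope * mx)

    rss <- function(A, T2) {
      E <- exp(-outer(1 / T2, te))
      rowSums((Sv - A * E)^2)
    }
    cost <- rss(A, T2)
    lam <- rep(1e-3, length(idx))
    for (it in seq_len(options$max_iterations)) {
      E <- exp(-outer(1 / T2, te))
      R <- Sv - A * E
      J1 <- E
      J2 <- (A / T2^2) * E * rep(te, each = nrow(E))
      a11 <- rowSums(J1 * J1); a22 <- rowSums(J2 * J2); a12 <- rowSums(J1 * J2)
      g1 <- rowSums(J1 * R); g2 <- rowSums(J2 * R)
      d11 <- a11 * (1 + lam); d22 <- a22 * (1 + lam)
      det <- d11 * d22 - a12^2
      det[abs(det) < 1e-300] <- 1e-300
      dA <- (d22 * g1 - a12 * g2) / det
      dT <- (d11 * g2 - a12 * g1) / det
      A2 <- A + dA
      T2n <- pmin(pmax(T2 + dT, lb), ub)
      cost2 <- rss(A2, T2n)
      better <- cost2 < cost
      A[better] <- A2[better]; T2[better] <- T2n[better]
      improve <- ifelse(cost > 0, (cost - cost2) / cost, 0)
      cost[better] <- cost2[better]
      lam <- ifelse(better, pmax(lam / 3, 1e-12), pmin(lam * 4, 1e10))
      if (all(!better | improve < options$convergence_tolerance)) break
    }
    t2[idx] <- T2
    amp[idx] <- A
    bound[idx] <- T2 <= lb + 1e-12 | T2 >= ub - 1e-12
  }
  mk <- function(x) { dim(x) <- d[1:3]; x }
  new("T2Map", t2 = mk(t2), amplitude = mk(amp), valid = mk(valid),
      atBound = mk(bound), bounds = options$t2_bounds)
}
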