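#' Correlation dimension (Grassberger-Procaccia)
#'
#' Estimates D2 from the correlation integral C(r): the fraction of state
#' pairs closer than r (temporal neighbours within the Theiler window
#' `m * tau` excluded). C(r) is evaluated on a 20-point log-spaced grid
#' between the 5th and 50th percentile of the pairwise distances, and D2 is
#' the slope of log C versus log r over the automatically selected scaling
#' region (the longest sub-range whose local slopes vary by less than 15
#' percent). When no such region exists the full-grid slope is returned
#' flagged unreliable.
#'
#' @param att an [embedSeries()] attractor with at least 100 states.
#' @param rquantiles distance percentiles bounding the r grid. The default
#'   (0.1 to 10 percent) keeps the grid in the small-distance regime where
#'   the correlation integral actually scales; macroscopic distances flatten
#'   the log-log curve below the true dimension.
#' @param ngrid number of r grid points.
#' @param maxStates at most this many states enter the pair counts (evenly
#'   strided subsample; estimator-level detail, the attractor is unchanged).
#' @return D2 estimate with attribute `reliable` (logical).
#' @export
correlationDimension <- function(att, rquantiles = c(0.001, 0.1), ngrid = 20L,
                                 maxStates = 1000L) {
  stopifnot(inherits(att, "Attractor"))
  M <- nrow(att)
  if (M < 100L) stop("need at least 100 states for D2 (got ", M, ")")
  theiler <- attr(att, "m") * attr(att, "tau")
  if (M > maxStates) {
    stride <- ceiling(M / maxStates)
    att <- att[seq(1L, M, by = stride), , drop = FALSE]
    theiler <- max(1L, ceiling(theiler / stride))
  }
  ds <- pairwise_dist_sample(unclass(att), as.integer(theiler), 50000L)
  if (!length(ds) || max(ds) == 0)
    stop("degenerate attractor: all states coincide")
  qs <- quantile(ds[ds > 0], rquantiles, names = FALSE)
  if (qs[1L] <= 0 || qs[2L] <= qs[1L])
    stop("degenerate attractor: no usable distance range")
  rg <- exp(seq(log(qs[1L]), log(qs[2L]), length.out = ngrid))
  C <- corr_integral(unclass(att), rg, as.integer(theiler))
  keep <- C > 0
  fit <- region_slope(log(rg[keep]), log(C[keep]))
  structure(fit$slope, reliable = fit$reliable)
}

#' Largest Lyapunov exponent (Rosenstein)
#'
#' For each reference state the nearest neighbour outside the Theiler
#' window `m * tau` is tracked for `kmax` steps; the mean log-divergence
#' curve is fitted over its best linear region (the same low-curvature
#' selection as [correlationDimension()], falling back to the initial
#' third of the curve) and the slope is converted to a per-second rate by
#' dividing by the sampling period.
#'
#' @param att an [embedSeries()] attractor with at least 200 states.
#' @param Ts sampling period in seconds (1 for maps).
#' @param kmax divergence horizon in steps (default: M / 10, at most 60).
#' @param maxref at most this many reference states (evenly strided).
#' @return LLE in units of 1/seconds, with attribute `reliable`.
#' @export
largestLyapunov <- function(att, Ts, kmax = NULL, maxref = 400L) {
  stopifnot(inherits(att, "Attractor"), Ts > 0)
  M <- nrow(att)
  if (M < 200L) stop("need at least 200 states for the LLE (got ", M, ")")
  theiler <- attr(att, "m") * attr(att, "tau")
  if (is.null(kmax)) kmax <- min(60L, max(10L, M %/% 10L))
  kmax <- min(as.integer(kmax), M - theiler - 2L)
  curve <- rosenstein_curve(unclass(att), as.integer(theiler), kmax,
                            as.integer(maxref))
  if (!length(curve)) stop("too few valid neighbour pairs for the LLE")
  k <- 0:kmax
  fit <- region_slope(k, curve, min_len = 5L)
  if (!fit$reliable) {
    ## fall back to the initial (pre-saturation) third of the curve
    idx <- seq_len(max(5L, (kmax + 1L) %/% 3L))
    fit <- list(slope = ls_slope(k[idx], curve[idx]), reliable = FALSE)
  }
  structure(fit$slope / Ts, reliable = fit$reliable)
}

#' Approximate entropy
#'
#' ApEn(m, r, N) of Pincus: the difference between the mean log template
#' match rates at lengths m and m+1, with Chebyshev distance, self-matches
#' included, and tolerance equal to `rFrac` times the series SD, so the
#' statistic is invariant to amplitude scaling. A zero-variance series returns 0 by
#' convention (a constant signal is perfectly regular).
#'
#' @param series numeric vector, length >= 100.
#' @param m template length (default 2).
#' @param rFrac tolerance as a fraction of the series SD (default 0.2).
#' @return non-negative ApEn value.
#' @export
#' @examples
#' approximateEntropy(sin(seq_len(256) / 5))
approximateEntropy <- function(series, m = 2L, rFrac = 0.2) {
  n <- length(series)
  if (n < 100L) stop("series too short for ApEn (need >= 100)")
  s <- sd(series)
  if (s == 0) return(0)
  phis <- apen_phis(series, as.integer(m), rFrac * s)
  phis[1L] - phis[2L]
}
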