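#' Hurst exponent by rescaled-range analysis
#'
#' Mean R/S statistic over non-overlapping segments at dyadic segment
#' sizes 16, 32, ... up to N/2; H is the slope of log(R/S) against
#' log(size). Estimates outside [0, 1] are clipped and flagged via the
#' `clipped` attribute.
#'
#' @param series numeric vector, length >= 256, non-constant.
#' @return H in [0, 1] with attribute `clipped`.
#' @seealso [dfa()] for the companion long-memory estimator.
#' @export
#' @examples
#' hurstRS(genFGN(0.8, 2048, seed = 1))
hurstRS <- function(series) {
  N <- length(series)
  if (N < 256L) stop("series too short for R/S analysis (need >= 256)")
  if (sd(series) == 0) stop("degenerate input: constant series (R/SD undefined)")
  cv <- rs_curve(series)
  h <- ls_slope(log(cv$sizes), log(cv$rs))
  clipped <- !is.na(h) && (h < 0 || h > 1)
  structure(min(max(h, 0), 1), clipped = clipped)
}

## mean R/S statistic over non-overlapping segments at dyadic sizes
rs_curve <- function(series) {
  N <- length(series)
  sizes <- 16L
  while (tail(sizes, 1L) * 2L <= N %/% 2L) sizes <- c(sizes, tail(sizes, 1L) * 2L)
  rs <- vapply(sizes, function(n) {
    k <- N %/% n
    vals <- vapply(seq_len(k), function(i) {
      seg <- series[((i - 1L) * n + 1L):(i * n)]
      S <- sd(seg)
      if (S == 0) return(NA_real_)
      y <- cumsum(seg - mean(seg))
      (max(y) - min(y)) / S
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  list(sizes = sizes, rs = rs)
}

#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-centred series into the cumulative deviation
#' profile, removes a least-squares line from each segment of size m, and
#' fits the log-log slope of the fluctuation function F(m) over 12
#' log-spaced sizes from 4 to N/4. For stationary fractional Gaussian
#' noise the exponent approximates the Hurst exponent; white noise gives
#' 0.5 and integrated white noise 1.5.
#'
#' @param series numeric vector, length >= 256, non-constant.
#' @param nscales number of log-spaced segment sizes.
#' @return the scaling exponent (often written alpha).
#' @export
#' @examples
#' dfa(rnorm(2048))
dfa <- function(series, nscales = 12L) {
  N <- length(series)
  if (N < 256L) stop("series too short for DFA (need >= 256)")
  if (sd(series) == 0) stop("degenerate input: constant series")
  ms <- unique(round(exp(seq(log(4), log(N / 4), length.out = nscales))))
  Fm <- dfa_fluctuation(series, ms)
  ls_slope(log(ms), log(Fm))
}

## fluctuation function F(m): RMS residual around a per-segment line fitted
## to the cumulative deviation profile
dfa_fluctuation <- function(series, ms) {
  N <- length(series)
  y <- cumsum(series - mean(series))
  vapply(ms, function(m) {
    k <- N %/% m
    tc <- seq_len(m) - (m + 1) / 2
    stt <- sum(tc^2)
    Y <- matrix(y[seq_len(k * m)], nrow = m)   # one segment per column
    Yc <- sweep(Y, 2L, colMeans(Y))
    b <- colSums(Yc * tc) / stt
    res2 <- colSums(Yc^2) - b^2 * stt
    sqrt(sum(res2) / (k * m))
  }, numeric(1))
}

#' Higuchi fractal dimension
#'
#' Curve lengths L(k) at scales k = 1..kmax (each the offset-average of
#' the standard normalized lag-k curve length), with the fractal dimension
#' given by the slope of ln L(k) against ln(1/k). A smooth curve gives 1,
#' white noise 2.
#'
#' @param series numeric vector of length >= 10 * kmax.
#' @param kmax largest scale (default 8).
#' @return FDh estimate.
#' @export
#' @examples
#' higuchiFD(rnorm(512))
higuchiFD <- function(series, kmax = 8L) {
  kmax <- as.integer(kmax)
  if (kmax < 2L) stop("kmax must be at least 2")
  N <- length(series)
  if (N < 10L * kmax) stop("series too short for Higuchi (need >= ", 10L * kmax, ")")
  Lk <- higuchi_lengths(series, kmax)
  ls_slope(log(1 / seq_len(kmax)), log(Lk))
}

## offset-averaged normalized curve length L(k) for k = 1..kmax
higuchi_lengths <- function(series, kmax) {
  N <- length(series)
  vapply(seq_len(kmax), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      i <- seq(m, N, by = k)
      if (length(i) < 2L) return(NA_real_)
      a <- length(i) - 1L
      sum(abs(diff(series[i]))) * (N - 1) / (a * k)
    }, numeric(1))
    mean(Lm, na.rm = TRUE) / k
  }, numeric(1))
}

#' Katz fractal dimension
#'
#' FDk = log(L/a) / log(d/a) on the planar curve of (index, value) pairs
#' with unit index step: L is the total length along successive points,
#' a the mean successive distance, and d the greatest distance from the
#' first point. An evenly spaced monotone line gives exactly 1.
#'
#' @param series numeric vector, length >= 3, with at least two distinct
#'   values.
#' @return FDk >= 1 for non-degenerate input.
#' @export
katzFD <- function(series) {
  N <- length(series)
  if (N < 3L) stop("series too short for Katz FD (need >= 3)")
  if (length(unique(series)) < 2L)
    stop("degenerate input: fewer than two distinct values")
  steps <- sqrt(1 + diff(series)^2)
  L <- sum(steps)
  a <- L / (N - 1L)
  i <- 2:N
  d <- max(sqrt((i - 1)^2 + (series[i] - series[1L])^2))
  if (d == 0 || L == 0) stop("degenerate input: zero extent")
  log(L / a) / log(d / a)
}

#' Signal energy
#'
#' Sum of squared amplitudes.
#'
#' @param series numeric vector.
#' @return non-negative energy.
#' @export
#' @examples
#' signalEnergy(c(1, 2, 2))  # 9
signalEnergy <- function(series) {
  if (!all(is.finite(series))) stop("non-finite values in series")
  sum(series^2)
}

ENTROPY_EPS <- 1e-12

#' Shannon (energy) entropy
#'
#' `-sum(|x|^2 * log(|x|^2))` with natural logarithm; samples with squared
#' amplitude below 1e-12 contribute 0. A discriminative statistic over
#' unnormalized energies, not a calibrated probability entropy.
#'
#' @param series numeric vector.
#' @param eps squared-amplitude floor.
#' @return ETs value.
#' @export
shannonEntropy <- function(series, eps = ENTROPY_EPS) {
  if (!all(is.finite(series))) stop("non-finite values in series")
  p <- series^2
  keep <- p >= eps
  -sum(p[keep] * log(p[keep]))
}

#' Log-energy entropy
#'
#' `-sum(log(|x|^2))` with natural logarithm; squared amplitudes below
#' 1e-12 are floored at 1e-12 before the logarithm. The sign follows the
#' convention that larger (super-unit) energies decrease the value.
#'
#' @param series numeric vector.
#' @param eps squared-amplitude floor.
#' @return ETL value.
#' @export
logEnergyEntropy <- function(series, eps = ENTROPY_EPS) {
  if (!all(is.finite(series))) stop("non-finite values in series")
  -sum(log(pmax(series^2, eps)))
}
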