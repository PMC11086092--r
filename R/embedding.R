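#' Estimate the embedding delay
#'
#' First well-defined local minimum of the auto mutual information
#' (equal-width histogram estimator, 16 bins) over lags 1..`cap`. A
#' minimum counts only when the curve both descends into it and rises out
#' of it by at least 1 percent of the curve's range within a five-lag
#' window, which rejects the sampling wiggles of structureless or flat AMI
#' curves. When the whole curve sits at the independence level (twice the
#' histogram bias, as for i.i.d. noise) the delay is 1; when no qualified
#' minimum exists (as for a pure oscillation, whose binned AMI is flat)
#' the first zero crossing of the autocorrelation function is used.
#' Capped at `length(series) / 10`.
#'
#' @param series numeric vector, length >= 64, non-constant.
#' @param nbins histogram bins for the mutual-information estimate.
#' @return integer delay in samples.
#' @seealso [estimateDimension()], [embedSeries()]
#' @export
estimateDelay <- function(series, nbins = 16L) {
  n <- length(series)
  if (n < 64L) stop("series too short for delay estimation (need >= 64)")
  if (sd(series) == 0) stop("degenerate input: constant series")
  cap <- max(1L, n %/% 10L)
  bx <- pmin(pmax(findInterval(series,
          seq(min(series), max(series), length.out = nbins + 1L),
          rightmost.closed = TRUE), 1L), nbins)
  ami <- function(lag) {
    a <- bx[seq_len(n - lag)]
    b <- bx[(lag + 1L):n]
    joint <- tabulate((a - 1L) * nbins + b, nbins * nbins) / (n - lag)
    pa <- tabulate(a, nbins) / (n - lag)
    pb <- tabulate(b, nbins) / (n - lag)
    pp <- as.vector(outer(pb, pa))   # matches tabulate's (a-1)*nbins+b order
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / pp[nz]))
  }
  vals <- vapply(seq_len(min(cap, 8L)), ami, numeric(1))
  bias <- (nbins - 1)^2 / (2 * n)     # Miller-Madow bias of the MI estimate
  if (max(vals) <= 2 * bias) return(1L)  # independent at every screened lag
  extend_to <- function(upto) {
    upto <- min(cap, upto)
    if (length(vals) < upto)
      vals <<- c(vals, vapply((length(vals) + 1L):upto, ami, numeric(1)))
  }
  found <- FALSE
  k <- 2L
  while (k < cap) {
    extend_to(3L * k)
    look <- (k + 1L):min(length(vals), k + 5L)
    ## first local minimum: no lower value within the next five lags
    if (vals[k] <= min(vals[look])) {
      descent <- max(vals[seq_len(k)]) - vals[k]
      if (descent > 0) {
        ## an oscillatory plateau (flat from right after the initial
        ## descent to the rise out of the minimum, as for a pure tone)
        ## has no well-defined minimum; a genuine minimum is preceded by
        ## curve structure on the scale of the descent
        ahead <- (k + 1L):min(length(vals), 3L * k)
        turned <- ahead[vals[ahead] >= vals[k] + 0.005 * descent]
        jend <- if (length(turned)) turned[1L] - 1L else max(ahead)
        plateau <- vals[2:max(2L, jend)]
        if (diff(range(plateau)) >= 0.05 * descent) {
          found <- TRUE
        }
        break  # flat plateau: fall through to the ACF rule
      }
    }
    k <- k + 1L
  }
  if (found) return(as.integer(k))
  ## no well-defined AMI minimum: first (statistical) zero crossing of
  ## the autocorrelation function
  ac <- acf(series, lag.max = cap, plot = FALSE, demean = TRUE)$acf[-1L]
  zc <- which(ac <= 1 / sqrt(n))
  if (length(zc)) return(as.integer(zc[1L]))
  cap
}

#' Estimate the embedding dimension by false nearest neighbours
#'
#' Smallest dimension `m <= mCap` whose false-nearest-neighbour fraction
#' falls below `threshold` (distance-ratio tolerance `rtol`, plus the usual
#' absolute criterion at two signal standard deviations, Theiler exclusion
#' `tau`). Returns `mCap` with a warning when the fraction never settles
#' (as for i.i.d. noise).
#'
#' @param series numeric vector.
#' @param tau embedding delay (from [estimateDelay()]).
#' @param mCap maximum dimension considered (default 10).
#' @param rtol false-neighbour distance-ratio tolerance (default 15).
#' @param threshold acceptable false-neighbour fraction (default 0.01).
#' @param maxref at most this many reference states are tested per
#'   dimension.
#' @return integer dimension, with attribute `fnn` (the fraction at the
#'   returned dimension).
#' @export
estimateDimension <- function(series, tau, mCap = 10L, rtol = 15,
                              threshold = 0.01, maxref = 200L) {
  n <- length(series)
  tau <- as.integer(tau)
  stopifnot(tau >= 1L)
  if (sd(series) == 0) stop("degenerate input: constant series")
  ## cap the probed dimension so at least a few extendable states remain
  mEff <- min(as.integer(mCap), (n - 16L) %/% tau)
  if (mEff < 1L)
    stop("series too short to probe any dimension at delay ", tau)
  frac <- fnn_fractions(series, tau, mEff, rtol,
                        2 * sd(series), as.integer(tau), as.integer(maxref),
                        threshold)
  if (all(is.na(frac)))
    stop("series too short to probe dimensions up to ", mCap,
         " at delay ", tau)
  ok <- which(!is.na(frac) & frac < threshold)
  if (length(ok)) {
    m <- ok[1L]
  } else {
    m <- max(which(!is.na(frac)))
    warning("false-nearest-neighbour fraction never fell below ",
            threshold, "; returning the cap m = ", m)
  }
  structure(as.integer(m), fnn = frac[m])
}

#' Time-delay embedding
#'
#' Builds the reconstructed attractor: row i is the delayed coordinate
#' vector `[x(i), x(i + tau), ..., x(i + (m-1) tau)]`, for
#' `i = 1..M`, `M = N - (m-1) tau`.
#'
#' @param series numeric vector of length N.
#' @param tau delay in samples (>= 1).
#' @param m embedding dimension (>= 1).
#' @return an `Attractor`: M x m numeric matrix with attributes `tau`, `m`,
#'   `N`.
#' @export
#' @examples
#' embedSeries(1:10, tau = 2, m = 3)
embedSeries <- function(series, tau, m) {
  n <- length(series)
  tau <- as.integer(tau); m <- as.integer(m)
  stopifnot(tau >= 1L, m >= 1L)
  M <- n - (m - 1L) * tau
  if (M < 1L)
    stop("embedding impossible: M = N - (m-1) tau = ", M, " < 1")
  X <- matrix(0, nrow = M, ncol = m)
  for (k in seq_len(m)) X[, k] <- series[((k - 1L) * tau + 1L):((k - 1L) * tau + M)]
  structure(X, tau = tau, m = m, N = n, class = c("Attractor", "matrix", "array"))
}

#' @export
print.Attractor <- function(x, ...) {
  cat(sprintf("Attractor: %d states in %d dimensions (tau = %d, N = %d)\n",
              nrow(x), attr(x, "m"), attr(x, "tau"), attr(x, "N")))
  invisible(x)
}
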