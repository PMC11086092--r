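#' Fractional Gaussian noise by circulant embedding
#'
#' Generates a stationary Gaussian series with self-similarity (Hurst)
#' exponent `hurst` and unit variance, using exact Davies-Harte circulant
#' embedding of the fGn autocovariance. When the circulant eigenvalues are
#' not all non-negative (does not occur for fGn in practice), an approximate
#' spectral-synthesis fallback is used and a warning is issued.
#'
#' `hurst = 0.5` reduces to white noise; `hurst > 0.5` gives persistent
#' (long-memory) noise, `hurst < 0.5` anti-persistent noise.
#'
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param n series length (>= 2).
#' @param seed optional integer seed; the global RNG stream is left intact.
#' @param sd marginal standard deviation of the series.
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' x <- genFGN(0.8, 1024, seed = 1)
#' var(x)
genFGN <- function(hurst, n, seed = NULL, sd = 1) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("hurst must lie strictly inside (0, 1)")
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  with_seed(seed, {
    ## circulant size: composite (fast FFT) and >= 2(n-1)
    m <- stats::nextn(2L * (n - 1L), factors = c(2L, 3L, 5L))
    k <- 0:(m %/% 2L)
    gam <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                    abs(k - 1)^(2 * hurst))
    lam <- Re(fft(c(gam, gam[(m %/% 2L):2])))
    if (min(lam) < -1e-8 * max(lam)) {
      warning("circulant embedding not non-negative definite; ",
              "falling back to approximate spectral synthesis")
      return(sd * fgn_spectral(hurst, n))
    }
    lam[lam < 0] <- 0
    half <- m / 2L
    a <- rnorm(half + 1L)
    b <- rnorm(half + 1L)
    W <- complex(length.out = m)
    W[1L] <- sqrt(lam[1L]) * a[1L]
    W[half + 1L] <- sqrt(lam[half + 1L]) * a[half + 1L]
    j <- 2:half
    W[j] <- sqrt(lam[j] / 2) * complex(real = a[j], imaginary = b[j])
    W[m + 2L - j] <- Conj(W[j])
    sd * Re(fft(W))[1:n] / sqrt(m)
  })
}

## Approximate fGn: shape white noise in the frequency domain by the
## square root of the fGn spectral density f^(1-2H), then renormalize.
fgn_spectral <- function(hurst, n) {
  nf <- n %/% 2L + 1L
  f <- seq(0, 0.5, length.out = nf)
  amp <- c(0, f[-1L]^((1 - 2 * hurst) / 2))
  ph <- runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  full <- c(spec, Conj(rev(spec[2:(nf - 1L)])))[1:n]
  x <- Re(fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / sd(x)
}

#' Deterministic chaotic test series
#'
#' Ground-truth orbits for validating the attractor-based estimators:
#' the logistic map x <- rx(1 - x) (largest Lyapunov exponent ln 2 at
#' parameter 4) and the x-coordinate of the Lorenz system integrated with a
#' fixed-step fourth-order Runge-Kutta scheme (correlation dimension about
#' 2.05 at the classic parameters).
#'
#' @param system `"logistic"` or `"lorenz"`.
#' @param n number of returned points (>= 100).
#' @param params named list. Logistic: `r` in (0, 4], `x0` in (0, 1).
#'   Lorenz: `sigma`, `rho`, `beta`, `dt` (integration step, seconds),
#'   `init` (length-3 state).
#' @param transient iterations/steps discarded before recording.
#' @param seed optional seed used only to jitter a missing initial condition.
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' head(genChaotic("logistic", 100, params = list(r = 4, x0 = 0.2), transient = 0))
genChaotic <- function(system = c("logistic", "lorenz"), n, params = list(),
                       transient = 1000L, seed = NULL) {
  if (!is.character(system) || !system[1L] %in% c("logistic", "lorenz"))
    stop("unknown system: ", system[1L])
  system <- match.arg(system)
  n <- as.integer(n)
  if (n < 100L) stop("n must be >= 100")
  transient <- as.integer(transient)
  if (system == "logistic") {
    r <- params$r %||% 4
    if (r <= 0 || r > 4) stop("logistic parameter r must lie in (0, 4]")
    x0 <- params$x0 %||% with_seed(seed, runif(1, 0.1, 0.9))
    if (x0 <= 0 || x0 >= 1) stop("initial condition x0 must lie in (0, 1)")
    total <- n + transient
    x <- numeric(total)
    x[1L] <- x0
    for (i in 2:total) x[i] <- r * x[i - 1L] * (1 - x[i - 1L])
    x[(transient + 1L):total]
  } else {
    sigma <- params$sigma %||% 10
    rho <- params$rho %||% 28
    beta <- params$beta %||% (8 / 3)
    dt <- params$dt %||% 0.01
    init <- params$init %||% with_seed(seed, c(1, 1, 1) + runif(3, -0.1, 0.1))
    deriv <- function(t, y, p) {
      list(c(p$sigma * (y[2L] - y[1L]),
             y[1L] * (p$rho - y[3L]) - y[2L],
             y[1L] * y[2L] - p$beta * y[3L]))
    }
    times <- seq(0, (n + transient) * dt, by = dt)
    out <- deSolve::ode(y = c(x = init[1L], y = init[2L], z = init[3L]),
                        times = times, func = deriv,
                        parms = list(sigma = sigma, rho = rho, beta = beta),
                        method = "rk4")
    out[(transient + 1L):(transient + n), "x"]
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Narrow-band oscillation for one EEG sub-band
#'
#' A randomized-phase sum of sinusoids on a fixed frequency comb inside the
#' band's nominal range, with a slow random-phase amplitude jitter,
#' normalized so the series RMS equals `amplitude`. The deterministic comb
#' keeps every realization's in-band power profile identical (realizations
#' differ by phases only). Comb frequencies sit on the `gridHz` grid
#' (default 0.2 Hz = one cycle per 5 s window), so each analysis window
#' sees whole cycles and the periodized transform sees no wrap-around
#' discontinuity. At least 90 percent of the spectral power lies inside
#' the band.
#'
#' @param band one of `bandNames()`.
#' @param fs sampling rate, Hz.
#' @param n series length.
#' @param amplitude RMS amplitude; `0` yields the all-zero series.
#' @param seed optional integer seed.
#' @param nComponents maximum number of sinusoidal components.
#' @param gridHz frequency grid the comb snaps to (default 0.2 Hz).
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' x <- genBandOscillation("alpha", fs = 256, n = 1280, seed = 1)
genBandOscillation <- function(band, fs, n, amplitude = 1, seed = NULL,
                               nComponents = 8L, gridHz = 0.2) {
  if (!is.character(band) || !band[1L] %in% BAND_NAMES)
    stop("unknown band: ", band[1L])
  band <- match.arg(band, BAND_NAMES)
  stopifnot(fs > 0, n > 0)
  n <- as.integer(n)
  if (amplitude == 0) return(numeric(n))
  rng <- BAND_RANGES[[band]]
  ## concentrate the comb near the band's effective centre (1.5x the lower
  ## octave edge, i.e. 6/12/24 Hz for theta/alpha/beta): an octave filter
  ## bank has wide transition bands, so edge frequencies would be split
  ## between neighbouring branches
  w <- diff(rng)
  centre <- if (band == "delta") mean(rng) else
    min(1.55 * rng[1L], rng[2L] - 0.1 * w)
  spread <- 0.05 * w
  lo <- max(centre - spread, rng[1L], 1.2 / (n / fs))
  hi <- min(centre + spread, rng[2L])
  if (hi <= lo) { lo <- rng[1L]; hi <- rng[2L] }
  freqs <- seq(ceiling(lo / gridHz) * gridHz, floor(hi / gridHz) * gridHz,
               by = gridHz)
  if (!length(freqs)) freqs <- round(mean(c(lo, hi)) / gridHz) * gridHz
  if (length(freqs) > nComponents)
    freqs <- freqs[unique(round(seq(1, length(freqs),
                                    length.out = nComponents)))]
  K <- length(freqs)
  with_seed(seed, {
    t <- seq_len(n) / fs
    phases <- runif(K, 0, 2 * pi)
    x <- colSums(t(sapply(seq_len(K), function(i)
      sin(2 * pi * freqs[i] * t + phases[i]))))
    ## slow multiplicative jitter, one cycle per analysis window
    env <- 1 + 0.15 * sin(2 * pi * gridHz * t + runif(1, 0, 2 * pi))
    x <- x * env
    amplitude * x / sqrt(mean(x^2))
  })
}
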