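## Biorthogonal 3.5 filter bank (decomposition low/high, reconstruction
## low/high). Standard published coefficients; the analysis low-pass has 12
## non-trivial taps, the spline-side filters 4.
BIOR35 <- list(
  dec_lo = c(-0.013810679320049757, 0.04143203796014927, 0.052480581416189075,
             -0.26792717880896527, -0.07181553246425873, 0.966747552403483,
             0.966747552403483, -0.07181553246425873, -0.26792717880896527,
             0.052480581416189075, 0.04143203796014927, -0.013810679320049757),
  dec_hi = c(0, 0, 0, 0, -0.1767766952966369, 0.5303300858899106,
             -0.5303300858899106, 0.1767766952966369, 0, 0, 0, 0),
  rec_lo = c(0, 0, 0, 0, 0.1767766952966369, 0.5303300858899106,
             0.5303300858899106, 0.1767766952966369, 0, 0, 0, 0),
  rec_hi = c(-0.013810679320049757, -0.04143203796014927, 0.052480581416189075,
             0.26792717880896527, -0.07181553246425873, -0.966747552403483,
             0.966747552403483, 0.07181553246425873, -0.26792717880896527,
             -0.052480581416189075, 0.04143203796014927, 0.013810679320049757))

## circular convolution by FFT; h is zero-padded to length(x)
circ_conv <- function(x, h) {
  n <- length(x)
  Re(fft(fft(x) * fft(c(h, numeric(n - length(h)))), inverse = TRUE)) / n
}

## One analysis step of the periodized filter bank. The downsampling phase
## (offset 11 = filter length - 1) makes the analysis/synthesis cascade
## delay-free, so multi-level reconstructions need no shift bookkeeping.
dwt_step <- function(x) {
  n <- length(x)
  idx <- ((2L * (0:(n %/% 2L - 1L)) + 11L) %% n) + 1L
  list(a = circ_conv(x, BIOR35$dec_lo)[idx],
       d = circ_conv(x, BIOR35$dec_hi)[idx])
}

idwt_step <- function(a, d) {
  n <- 2L * length(a)
  up_a <- numeric(n); up_d <- numeric(n)
  up_a[seq(1L, n, by = 2L)] <- a
  up_d[seq(1L, n, by = 2L)] <- d
  circ_conv(up_a, BIOR35$rec_lo) + circ_conv(up_d, BIOR35$rec_hi)
}

#' Discrete wavelet decomposition (biorthogonal 3.5, periodized)
#'
#' Five-level octave-band, critically decimated analysis of one series with
#' the biorthogonal 3.5 filter pair and periodic (circular) boundary
#' handling, which gives exact perfect reconstruction and bit-stable
#' coefficient lengths: level j holds `length(series) / 2^j` detail
#' coefficients (a 1280-sample window yields a level-5 approximation of
#' exactly 40 coefficients).
#'
#' @param series numeric vector; its length must be divisible by
#'   `2^levels` and at least `2^levels`.
#' @param wavelet filter-bank name; only `"bior3.5"` is built in.
#' @param levels decomposition depth (default 5).
#' @return A `WaveletPyramid`: list with elements `d1..d<levels>` (details,
#'   finest first), `a<levels>` (approximation), and attributes `wavelet`,
#'   `mode`, `n`.
#' @seealso [reconstructSubband()], [decomposeToSubbands()]
#' @export
#' @examples
#' p <- dwtDecompose(sin(2 * pi * 10 * seq_len(1280) / 256))
#' lengths(p)
dwtDecompose <- function(series, wavelet = "bior3.5", levels = 5L) {
  if (!identical(wavelet, "bior3.5"))
    stop("only the bior3.5 filter bank is built in")
  levels <- as.integer(levels)
  n <- length(series)
  if (n < 2^levels)
    stop("series too short: need at least ", 2^levels, " samples for ",
         levels, " levels")
  if (n %% 2^levels != 0L)
    stop("series length must be divisible by 2^levels = ", 2^levels,
         " (periodized transform); got ", n)
  if (!all(is.finite(series))) stop("non-finite values in series")
  out <- vector("list", levels + 1L)
  names(out) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  a <- as.numeric(series)
  for (l in seq_len(levels)) {
    s <- dwt_step(a)
    out[[l]] <- s$d
    a <- s$a
  }
  out[[levels + 1L]] <- a
  structure(out, wavelet = wavelet, mode = "periodization", n = n,
            class = "WaveletPyramid")
}

#' @export
print.WaveletPyramid <- function(x, ...) {
  cat(sprintf("WaveletPyramid (%s, %s): n = %d; coefficients: %s\n",
              attr(x, "wavelet"), attr(x, "mode"), attr(x, "n"),
              paste(sprintf("%s[%d]", names(x), lengths(x)), collapse = " ")))
  invisible(x)
}

## band <-> branch map at fs = 256 Hz
BAND_BRANCH <- c(delta = "a5", theta = "d5", alpha = "d4", beta = "d3",
                 gamma = "d2")

## single-branch inverse transform for any named branch (d1..d5, a5)
reconstruct_branch <- function(pyramid, branch) {
  levels <- length(pyramid) - 1L
  if (branch == paste0("a", levels)) {
    cur <- pyramid[[branch]]
    for (l in seq_len(levels)) cur <- idwt_step(cur, numeric(length(cur)))
    return(cur)
  }
  l0 <- as.integer(sub("^d", "", branch))
  cur <- idwt_step(numeric(length(pyramid[[branch]])), pyramid[[branch]])
  while (l0 > 1L) {
    cur <- idwt_step(cur, numeric(length(cur)))
    l0 <- l0 - 1L
  }
  cur
}

#' Reconstruct one EEG sub-band from a wavelet pyramid
#'
#' Single-branch inverse transform of the branch carrying the requested
#' band at 256 Hz: gamma from D2 (32--64 Hz; content above 45 Hz is removed
#' by the upstream low-pass), beta from D3 (16--32), alpha from D4 (8--16),
#' theta from D5 (4--8) and delta from A5 (0--4). The output has the length
#' of the analyzed window.
#'
#' @param pyramid a [dwtDecompose()] result with 5 levels.
#' @param band one of `bandNames()`, or `"d1"` for the discarded 64--128 Hz
#'   branch (useful for reconstruction checks).
#' @return numeric vector.
#' @export
reconstructSubband <- function(pyramid, band) {
  stopifnot(inherits(pyramid, "WaveletPyramid"))
  if (identical(band, "d1")) return(reconstruct_branch(pyramid, "d1"))
  if (!is.character(band) || !band[1L] %in% BAND_NAMES)
    stop("unknown band: ", band[1L])
  band <- match.arg(band, BAND_NAMES)
  if (length(pyramid) != 6L)
    stop("band reconstruction expects a 5-level pyramid")
  reconstruct_branch(pyramid, BAND_BRANCH[[band]])
}

#' Decompose all windows and channels into the five sub-bands
#'
#' Runs the five-level bior3.5 analysis and single-branch reconstruction on
#' every (channel, window) series of a [WindowSet-class] at 256 Hz. The D1
#' branch (64--128 Hz) is discarded.
#'
#' @param windowset a [WindowSet-class]; `samplingRate` must be 256, the
#'   rate the band-to-level map is defined for.
#' @return A [SubbandWindowSet-class].
#' @export
decomposeToSubbands <- function(windowset) {
  stopifnot(is(windowset, "WindowSet"))
  if (abs(samplingRate(windowset) - 256) > 1e-9)
    stop("the band-to-level map requires fs = 256 Hz; resample first")
  d <- dim(windowset@windows)
  out <- array(0, dim = c(d[1L], d[2L], d[3L], 5L),
               dimnames = list(NULL, NULL, NULL, BAND_NAMES))
  for (w in seq_len(d[3L])) {
    for (ch in seq_len(d[1L])) {
      pyr <- dwtDecompose(windowset@windows[ch, , w])
      for (b in seq_along(BAND_NAMES))
        out[ch, , w, b] <- reconstruct_branch(pyr, BAND_BRANCH[[BAND_NAMES[b]]])
    }
  }
  new("SubbandWindowSet", series = out, fs = samplingRate(windowset),
      labels = channelLabels(windowset))
}
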