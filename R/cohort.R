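#' Configuration for a synthetic two-group EEG cohort
#'
#' Describes the study conditions of a simulated cohort: two groups of
#' subjects, recording geometry (channels, sampling rate, duration), and an
#' optional set of group effects injected into the second group.
#'
#' Each channel is generated as a sum over the five sub-bands of a
#' narrow-band oscillation plus band-confined fractional-Gaussian background
#' noise, mixed 1:1 in amplitude at the default Hurst exponent. Effects act
#' on the generator parameters of the second group at one (channel, band):
#' \describe{
#'   \item{hurst}{adds `magnitude` to the Hurst exponent of the unit-variance
#'     fGn feeding that band's noise. The band component is not renormalized,
#'     so the shift expresses the physical consequences of longer memory:
#'     the band's energy share and in-band spectral tilt change.}
#'   \item{energy}{multiplies the band's energy by `1 + magnitude`.}
#'   \item{irregularity}{moves the band's oscillation:noise variance balance
#'     toward noise by `magnitude` (total band energy preserved).}
#' }
#'
#' @param nPerGroup integer(2), subjects per group.
#' @param groups character(2), group labels; labels ending in "G" are treated
#'   as good sleepers when drawing pseudo-PSQI scores (0..5 versus 6..15).
#' @param nChannels number of channels (default 32).
#' @param fs sampling rate in Hz (default 256).
#' @param duration recording length in seconds (default 60).
#' @param effects data.frame with columns `channel` (index), `band`,
#'   `family` (one of `"hurst"`, `"energy"`, `"irregularity"`) and
#'   `magnitude`; `NULL` for a null cohort.
#' @param hurst0 baseline Hurst exponent of the band noise (default 0.6,
#'   mid-range of the persistent exponents typical of awake EEG; keeps the
#'   shifted exponent of a +0.25 hurst effect well inside (0, 1)).
#' @param oscGain,noiseGain global amplitude gains of the oscillatory and
#'   noise parts (defaults 1 and 1: equal-amplitude mixing).
#' @param seed integer seed driving all randomness of [genCohort()].
#' @return A `CohortConfig` object.
#' @seealso [genCohort()]
#' @export
#' @examples
#' cfg <- cohortConfig(c(4, 4), nChannels = 2, duration = 10, seed = 1)
cohortConfig <- function(nPerGroup, groups = c("YG", "OB"), nChannels = 32L,
                         fs = 256, duration = 60, effects = NULL,
                         hurst0 = 0.6, oscGain = 1, noiseGain = 1, seed = 1L) {
  nPerGroup <- as.integer(nPerGroup)
  if (length(nPerGroup) != 2L || any(nPerGroup < 1L))
    stop("nPerGroup must be two positive integers")
  if (length(groups) != 2L || anyDuplicated(groups))
    stop("groups must be two distinct labels")
  nChannels <- as.integer(nChannels)
  if (nChannels < 1L) stop("nChannels must be positive")
  if (fs <= 0 || duration <= 0) stop("fs and duration must be positive")
  n <- duration * fs
  if (abs(n - round(n)) > 1e-8) stop("duration * fs must be an integer sample count")
  if (hurst0 <= 0 || hurst0 >= 1) stop("hurst0 must lie in (0, 1)")
  if (is.null(effects)) {
    effects <- data.frame(channel = integer(), band = character(),
                          family = character(), magnitude = numeric())
  } else {
    effects <- as.data.frame(effects)
    need <- c("channel", "band", "family", "magnitude")
    if (!all(need %in% names(effects)))
      stop("effects needs columns: ", paste(need, collapse = ", "))
    if (any(effects$channel < 1L | effects$channel > nChannels))
      stop("effect channel index outside 1..nChannels")
    if (!all(effects$band %in% BAND_NAMES))
      stop("unknown effect band: ",
           paste(setdiff(effects$band, BAND_NAMES), collapse = ", "))
    if (!all(effects$family %in% c("hurst", "energy", "irregularity")))
      stop("unknown effect family: ",
           paste(setdiff(effects$family, c("hurst", "energy", "irregularity")),
                 collapse = ", "))
    hh <- effects$family == "hurst"
    if (any(hurst0 + effects$magnitude[hh] <= 0 |
              hurst0 + effects$magnitude[hh] >= 1))
      stop("hurst effect pushes the Hurst exponent outside (0, 1)")
  }
  structure(
    list(nPerGroup = nPerGroup, groups = as.character(groups),
         nChannels = nChannels, fs = fs, duration = duration,
         nSamples = as.integer(round(n)), effects = effects, hurst0 = hurst0,
         oscGain = oscGain, noiseGain = noiseGain, seed = as.integer(seed)),
    class = "CohortConfig")
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat(sprintf("CohortConfig: %s (n=%d) vs %s (n=%d), %d channels, %g Hz, %g s, seed %d\n",
              x$groups[1L], x$nPerGroup[1L], x$groups[2L], x$nPerGroup[2L],
              x$nChannels, x$fs, x$duration, x$seed))
  if (nrow(x$effects)) {
    cat(" effects on", x$groups[2L], "\n")
    print(x$effects, row.names = FALSE)
  } else cat(" null cohort (no injected effects)\n")
  invisible(x)
}

## Circulant-embedding eigenvalues of the fGn autocovariance (the spectral
## weights used for synthesis) plus the folded frequency of each bin.
fgn_spectrum <- function(hurst, n, fs) {
  m <- stats::nextn(2L * (n - 1L), factors = c(2L, 3L, 5L))
  k <- 0:(m %/% 2L)
  gam <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
  lam <- pmax(Re(fft(c(gam, gam[(m %/% 2L):2]))), 0)
  f <- (0:(m - 1L)) / m * fs
  list(lam = lam, f = pmin(f, fs - f), m = m)
}

## Fraction of fGn variance falling inside a band (deterministic).
fgn_band_share <- function(hurst, n, fs, band, spec = NULL) {
  if (is.null(spec)) spec <- fgn_spectrum(hurst, n, fs)
  rng <- BAND_RANGES[[band]]
  sel <- spec$f >= rng[1L] & spec$f < rng[2L]
  sum(spec$lam[sel]) / sum(spec$lam)
}

## Band-confined fGn-like noise: spectral synthesis on the circulant
## frequency grid with the fGn spectral weights, deterministic amplitudes
## and randomized phases (surrogate-data style), normalized so the
## realization's SD equals exactly sqrt(band share). Deterministic
## amplitudes pin each subject's band and branch energies at the process
## expectation: between-subject variability is phase noise only, so
## injected parameter shifts -- not spectral amplitude lottery -- drive
## group differences.
gen_band_fgn <- function(spec, band, n, fs) {
  rng <- BAND_RANGES[[band]]
  sel <- spec$f >= rng[1L] & spec$f < rng[2L]
  lam <- spec$lam * sel
  m <- spec$m
  half <- m %/% 2L
  phi <- runif(half + 1L, 0, 2 * pi)
  W <- complex(length.out = m)
  W[1L] <- sqrt(lam[1L]) * sign(cos(phi[1L]))
  W[half + 1L] <- sqrt(lam[half + 1L]) * sign(cos(phi[half + 1L]))
  j <- 2:half
  W[j] <- sqrt(lam[j]) * exp(1i * phi[j])
  W[m + 2L - j] <- Conj(W[j])
  x <- Re(fft(W))[1:n] / sqrt(m)
  share <- sum(lam) / sum(spec$lam)
  s <- sd(x)
  if (s == 0) return(x)
  x * sqrt(share) / s
}

#' Generate a synthetic two-group EEG cohort
#'
#' Simulates one [EEGRecording-class] per subject plus a labeled subject
#' table. All randomness is driven by `config$seed`: identical configs give
#' bit-identical cohorts. Subjects are i.i.d. realizations of their group's
#' generative process; between-subject variability is pure realization noise,
#' which keeps the null calibrated and makes injected effects interpretable.
#'
#' @param config a [cohortConfig()] object.
#' @return list with elements `recordings` (named list of
#'   [EEGRecording-class]) and `subjects` (data.frame: subject, group, psqi).
#' @export
#' @examples
#' coh <- genCohort(cohortConfig(c(2, 2), nChannels = 2, duration = 10, seed = 7))
#' coh$subjects
genCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$nSamples
  fs <- config$fs
  ## spectral machinery per distinct Hurst exponent in play
  hs <- unique(c(config$hurst0,
                 config$hurst0 + config$effects$magnitude[
                   config$effects$family == "hurst"]))
  specs <- lapply(setNames(hs, sprintf("%.10g", hs)), fgn_spectrum, n = n, fs = fs)
  spec0 <- specs[[sprintf("%.10g", config$hurst0)]]
  ## per-band noise SD at the baseline Hurst exponent; fixes the 1:1
  ## oscillation:noise amplitude calibration
  base_sd <- vapply(BAND_NAMES, function(b)
    sqrt(fgn_band_share(config$hurst0, n, fs, b, spec = spec0)), numeric(1))
  groups <- rep(config$groups, config$nPerGroup)
  ids <- sprintf("%s%02d", groups, unlist(lapply(config$nPerGroup, seq_len)))
  good <- grepl("G$", groups)

  eff <- config$effects
  eff_at <- function(ch, band, family) {
    i <- which(eff$channel == ch & eff$band == band & eff$family == family)
    if (length(i)) sum(eff$magnitude[i]) else 0
  }

  recordings <- with_seed(config$seed, {
    psqi <- ifelse(good, sample(0:5, length(ids), replace = TRUE),
                   sample(6:15, length(ids), replace = TRUE))
    recs <- vector("list", length(ids))
    for (s in seq_along(ids)) {
      affected <- groups[s] == config$groups[2L]
      dat <- matrix(0, nrow = config$nChannels, ncol = n)
      for (ch in seq_len(config$nChannels)) {
        x <- numeric(n)
        for (b in BAND_NAMES) {
          h <- config$hurst0
          osc_sc <- 1; noi_sc <- 1
          if (affected) {
            h <- h + eff_at(ch, b, "hurst")
            en <- eff_at(ch, b, "energy")
            osc_sc <- osc_sc * sqrt(1 + en)
            noi_sc <- noi_sc * sqrt(1 + en)
            irr <- eff_at(ch, b, "irregularity")
            if (irr != 0) {
              rho <- 0.5  # baseline noise variance fraction of the band
              rho2 <- min(0.999, max(0.001, rho + irr))
              osc_sc <- osc_sc * sqrt((1 - rho2) / (1 - rho))
              noi_sc <- noi_sc * sqrt(rho2 / rho)
            }
          }
          noise <- gen_band_fgn(specs[[sprintf("%.10g", h)]], b, n, fs)
          osc <- genBandOscillation(b, fs, n,
                                    amplitude = config$oscGain * base_sd[[b]])
          x <- x + osc_sc * osc + noi_sc * config$noiseGain * noise
        }
        dat[ch, ] <- x
      }
      recs[[s]] <- EEGRecording(dat, fs = fs,
                                labels = paste0("Ch", seq_len(config$nChannels)))
    }
    names(recs) <- ids
    attr(recs, "psqi") <- psqi
    recs
  })
  psqi <- attr(recordings, "psqi")
  attr(recordings, "psqi") <- NULL
  list(recordings = recordings,
       subjects = data.frame(subject = ids, group = groups,
                             psqi = as.integer(psqi)))
}

#' Write a cohort to disk
#'
#' One recording file per subject (EDF or delimited text matrix with a JSON
#' sidecar), plus `subjects.tsv` (subject, group, psqi) and `config.txt`
#' (key-value record of the generating configuration).
#'
#' @param cohort result of [genCohort()].
#' @param dir output directory (created if needed).
#' @param format `"matrix"` (text) or `"edf"`.
#' @param config optional [cohortConfig()] recorded alongside the data.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("matrix", "edf"),
                        config = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    path <- file.path(dir, paste0(id, if (format == "edf") ".edf" else ".txt"))
    writeRecording(cohort$recordings[[id]], path, format = format)
  }
  write.table(cohort$subjects, file.path(dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    keys <- c(nPerGroup = paste(config$nPerGroup, collapse = ","),
              groups = paste(config$groups, collapse = ","),
              nChannels = config$nChannels, fs = config$fs,
              duration = config$duration, hurst0 = config$hurst0,
              oscGain = config$oscGain, noiseGain = config$noiseGain,
              seed = config$seed)
    writeLines(paste(names(keys), keys, sep = " = "),
               file.path(dir, "config.txt"))
  }
  invisible(dir)
}
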