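#' Names of the ten non-linear features
#'
#' D2 (correlation dimension), LLE (largest Lyapunov exponent, 1/s), ApEn
#' (approximate entropy), H (rescaled-range Hurst exponent), DFA
#' (detrended-fluctuation exponent), FDh and FDk (Higuchi and Katz fractal
#' dimensions), EN (energy), ETs and ETL (Shannon and log-energy
#' entropies).
#'
#' @return character vector of length 10.
#' @export
featureNames <- function() {
  c("D2", "LLE", "ApEn", "H", "DFA", "FDh", "FDk", "EN", "ETs", "ETL")
}

#' Tunable parameters of the feature extractors
#'
#' One place for every estimator tunable; the defaults are the values used
#' throughout the package.
#'
#' @param kmax Higuchi largest scale.
#' @param rFrac ApEn tolerance as a fraction of the series SD.
#' @param mCap embedding-dimension cap for false nearest neighbours.
#' @param rQuantiles distance percentiles bounding the D2 r-grid.
#' @param nGrid D2 r-grid size.
#' @param entropyEps floor for squared amplitudes inside the entropies.
#' @param d2MaxStates state subsample cap inside [correlationDimension()].
#' @param lleMaxRef reference-state cap inside [largestLyapunov()].
#' @param fnnMaxRef reference-state cap inside [estimateDimension()].
#' @return a named list.
#' @export
featureOptions <- function(kmax = 8L, rFrac = 0.2, mCap = 10L,
                           rQuantiles = c(0.001, 0.1), nGrid = 20L,
                           entropyEps = 1e-12, d2MaxStates = 450L,
                           lleMaxRef = 200L, fnnMaxRef = 150L) {
  list(kmax = kmax, rFrac = rFrac, mCap = mCap, rQuantiles = rQuantiles,
       nGrid = nGrid, entropyEps = entropyEps, d2MaxStates = d2MaxStates,
       lleMaxRef = lleMaxRef, fnnMaxRef = fnnMaxRef)
}

#' Extract the ten non-linear features from one band series
#'
#' Estimates the embedding delay and dimension once for the series, embeds
#' it, and computes the full feature set. Per-feature failures (degenerate
#' input, too few states, missing scaling region) are reported in the
#' `status` vector rather than aborting the whole window: failed features
#' carry `NA` values with a reason, and an unreliable scaling region is
#' flagged but keeps its value.
#'
#' @param series numeric vector (a 5 s band-limited window, typically 1280
#'   samples).
#' @param fs sampling rate in Hz (sets the Lyapunov time unit).
#' @param opts a [featureOptions()] list.
#' @return list with `values` (named numeric, length 10), `status` (named
#'   character: "ok", "unreliable", "degenerate" or "error: ..."), `tau`
#'   and `m` (the embedding parameters, NA when not estimable).
#' @export
#' @examples
#' f <- extractFeatures(genFGN(0.7, 1280, seed = 1), fs = 256)
#' f$values
extractFeatures <- function(series, fs, opts = featureOptions()) {
  feats <- featureNames()
  values <- setNames(rep(NA_real_, length(feats)), feats)
  status <- setNames(rep("ok", length(feats)), feats)

  grab <- function(name, expr) {
    res <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- if (grepl("degenerate", conditionMessage(res)))
        "degenerate" else paste0("error: ", conditionMessage(res))
    } else {
      values[[name]] <<- as.numeric(res)
      rel <- attr(res, "reliable")
      if (!is.null(rel) && !rel) status[[name]] <<- "unreliable"
    }
  }

  ## series-based features need no embedding
  grab("EN", signalEnergy(series))
  grab("ETs", shannonEntropy(series, eps = opts$entropyEps))
  grab("ETL", logEnergyEntropy(series, eps = opts$entropyEps))
  grab("FDk", katzFD(series))
  grab("FDh", higuchiFD(series, kmax = opts$kmax))
  grab("H", hurstRS(series))
  grab("DFA", dfa(series))

  constant <- sd(series) == 0
  if (constant) {
    values[["ApEn"]] <- 0  # perfectly regular by convention
    status[c("D2", "LLE")] <- "degenerate"
    status[c("H", "DFA", "FDh", "FDk")] <- "degenerate"
    return(list(values = values, status = status,
                tau = NA_integer_, m = NA_integer_))
  }
  grab("ApEn", approximateEntropy(series, rFrac = opts$rFrac))

  tau <- tryCatch(estimateDelay(series), error = function(e) NA_integer_)
  m <- if (is.na(tau)) NA_integer_ else
    tryCatch(suppressWarnings(estimateDimension(series, tau, mCap = opts$mCap,
                                                maxref = opts$fnnMaxRef)),
             error = function(e) NA_integer_)
  if (is.na(tau) || is.na(m)) {
    status[c("D2", "LLE")] <- "degenerate"
    return(list(values = values, status = status, tau = tau, m = m))
  }
  att <- embedSeries(series, tau, m)
  grab("D2", correlationDimension(att, rquantiles = opts$rQuantiles,
                                  ngrid = opts$nGrid,
                                  maxStates = opts$d2MaxStates))
  grab("LLE", largestLyapunov(att, Ts = 1 / fs, maxref = opts$lleMaxRef))
  list(values = values, status = status, tau = as.integer(tau),
       m = as.integer(m))
}
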