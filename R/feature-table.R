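#' Per-window feature extraction for a whole cohort
#'
#' Runs the full per-subject pipeline: optional band-pass / DC removal,
#' first-minute selection, 5 s windowing, sub-band decomposition, and the
#' ten-feature extraction on every (channel, window, band) series.
#'
#' @param recordings named list of [EEGRecording-class] (one per subject).
#' @param bandpass apply [bandpassDC()] first (default TRUE; synthetic
#'   cohorts are already band-limited, so FALSE skips a costly no-op).
#' @param firstMinute restrict to the first 60 s when longer.
#' @param windowDuration window length in seconds (default 5).
#' @param opts a [featureOptions()] list.
#' @param verbose print one progress line per subject.
#' @return data.frame with columns subject, channel, band, window, feature,
#'   value, status, tau, m.
#' @seealso [aggregateWindows()] for the per-subject summary table.
#' @export
extractCohortFeatures <- function(recordings, bandpass = TRUE,
                                  firstMinute = TRUE, windowDuration = 5,
                                  opts = featureOptions(), verbose = FALSE) {
  stopifnot(is.list(recordings), length(recordings) > 0)
  if (is.null(names(recordings)))
    names(recordings) <- paste0("S", seq_along(recordings))
  out <- vector("list", length(recordings))
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    stopifnot(is(rec, "EEGRecording"))
    if (bandpass) rec <- bandpassDC(rec)
    if (firstMinute && nSamples(rec) / samplingRate(rec) > 60)
      rec <- selectFirstMinute(rec)
    sbs <- decomposeToSubbands(windowRecording(rec, duration = windowDuration))
    nw <- nWindows(sbs)
    nch <- nChannels(sbs)
    nf <- length(featureNames())
    ncell <- nch * nw * 5L
    value <- numeric(ncell * nf); status <- character(ncell * nf)
    tau_ <- integer(ncell); m_ <- integer(ncell)
    chv <- character(ncell); bv <- character(ncell); wv <- integer(ncell)
    r <- 0L
    for (ch in seq_len(nch)) {
      for (w in seq_len(nw)) {
        for (b in BAND_NAMES) {
          f <- extractFeatures(bandSeries(sbs, ch, w, b),
                               fs = samplingRate(sbs), opts = opts)
          r <- r + 1L
          sl <- ((r - 1L) * nf + 1L):(r * nf)
          value[sl] <- unname(f$values); status[sl] <- unname(f$status)
          tau_[r] <- f$tau; m_[r] <- f$m
          chv[r] <- channelLabels(sbs)[ch]; bv[r] <- b; wv[r] <- w
        }
      }
    }
    out[[s]] <- data.frame(
      subject = names(recordings)[s], channel = rep(chv, each = nf),
      band = rep(bv, each = nf), window = rep(wv, each = nf),
      feature = rep(featureNames(), ncell), value = value, status = status,
      tau = rep(tau_, each = nf), m = rep(m_, each = nf))
    if (verbose)
      message(sprintf("features: subject %s (%d/%d) done",
                      names(recordings)[s], s, length(recordings)))
  }
  do.call(rbind, out)
}

#' Aggregate window-level features to one value per subject cell
#'
#' Window-mean per (subject, channel, band, feature), using only windows
#' whose status is "ok" or "unreliable"; the number of contributing
#' windows is recorded. Cells with no valid window become missing (NA)
#' with status "missing".
#'
#' @param perWindow the [extractCohortFeatures()] table.
#' @param subjects data.frame with columns subject, group, psqi.
#' @return a [CohortFeatureTable-class].
#' @export
aggregateWindows <- function(perWindow, subjects) {
  stopifnot(is.data.frame(perWindow), nrow(perWindow) > 0)
  ok <- !is.na(perWindow$value) &
    perWindow$status %in% c("ok", "unreliable")
  key <- c("subject", "channel", "band", "feature")
  full <- unique(perWindow[key])
  if (any(ok)) {
    agg <- aggregate(perWindow$value[ok], by = perWindow[ok, key],
                     FUN = mean)
    cnt <- aggregate(perWindow$value[ok], by = perWindow[ok, key],
                     FUN = length)
    names(agg)[5L] <- "value"
    names(cnt)[5L] <- "nWindows"
    tb <- merge(full, merge(agg, cnt, by = key, all = TRUE),
                by = key, all.x = TRUE)
  } else {
    tb <- full
    tb$value <- NA_real_
    tb$nWindows <- NA_integer_
  }
  tb$nWindows[is.na(tb$nWindows)] <- 0L
  tb$status <- ifelse(tb$nWindows > 0L, "ok", "missing")
  tb <- tb[order(tb$subject, tb$channel, tb$band, tb$feature), ]
  rownames(tb) <- NULL
  new("CohortFeatureTable", table = tb,
      subjects = as.data.frame(subjects))
}

#' Define a pair of groups to compare
#'
#' @param table a [CohortFeatureTable-class].
#' @param groupA,groupB the two group labels.
#' @return list with the pair name, labels, and subject ids per side.
#' @export
groupPair <- function(table, groupA, groupB) {
  stopifnot(is(table, "CohortFeatureTable"))
  si <- subjectInfo(table)
  if (identical(groupA, groupB)) stop("pair sides must differ")
  a <- si$subject[si$group == groupA]
  b <- si$subject[si$group == groupB]
  if (!length(a) || !length(b))
    stop("empty group side: ", if (!length(a)) groupA else groupB)
  list(name = paste0(groupA, "_vs_", groupB), groups = c(groupA, groupB),
       subjectsA = a, subjectsB = b)
}

#' Z-score a feature table for one group pair
#'
#' Pools the two groups' subjects and, per (channel, band, feature) cell,
#' subtracts the pooled mean and divides by the pooled standard deviation
#' (denominator n - 1). Zero-variance cells are set to 0 with a warning.
#' Missing values are ignored in the statistics and propagated.
#'
#' Pooling both groups before cross-validation leaks distributional
#' information into a later LOOCV; see [runPair()]'s `normalization =
#' "foldwise"` for the leakage-free variant.
#'
#' @param table a [CohortFeatureTable-class].
#' @param pair a [groupPair()].
#' @return a [CohortFeatureTable-class] restricted to the pair's subjects,
#'   with z-scored values.
#' @export
zscorePair <- function(table, pair) {
  stopifnot(is(table, "CohortFeatureTable"))
  tb <- featureTable(table)
  keep <- tb$subject %in% c(pair$subjectsA, pair$subjectsB)
  tb <- tb[keep, ]
  if (length(unique(tb$subject)) < 3L)
    stop("need at least 3 pooled subjects to z-score")
  key <- interaction(tb$channel, tb$band, tb$feature, drop = TRUE)
  mu <- tapply(tb$value, key, mean, na.rm = TRUE)
  sg <- tapply(tb$value, key, sd, na.rm = TRUE)
  z <- (tb$value - mu[key]) / sg[key]
  flat <- !is.na(sg[key]) & sg[key] == 0
  if (any(flat, na.rm = TRUE)) {
    warning(sum(tapply(flat, key, any)), " zero-variance cell(s) set to 0")
    z[flat] <- 0
  }
  tb$value <- as.numeric(z)
  si <- subjectInfo(table)
  new("CohortFeatureTable", table = tb,
      subjects = si[si$subject %in% unique(tb$subject), ])
}
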