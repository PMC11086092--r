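#' Zero-phase band-pass filtering with DC removal
#'
#' Applies a zero-phase (forward-backward) windowed-sinc FIR band-pass
#' between `lo` and `hi` to every channel, then removes any residual DC
#' offset exactly by subtracting the channel mean. The FIR realization is
#' the standard choice for EEG preprocessing: linear phase (hence exactly
#' zero phase when applied forward-backward) and a controlled transition
#' band, so that non-linear features downstream are not distorted by
#' filter phase.
#'
#' The filter order defaults to `fs * 1.5` (about a 2.2 Hz transition band
#' at 256 Hz) and is reduced automatically for short signals.
#'
#' @param rec an [EEGRecording-class].
#' @param lo,hi corner frequencies in Hz (defaults 0.1 and 45).
#' @param order optional FIR order override (even integer).
#' @return filtered [EEGRecording-class] with per-channel mean zero.
#' @export
bandpassDC <- function(rec, lo = 0.1, hi = 45, order = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (hi >= fs / 2) stop("hi corner must be below the Nyquist frequency ", fs / 2)
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi")
  n <- nSamples(rec)
  if (is.null(order)) order <- round(fs * 1.5)
  order <- min(order, floor((n - 4) / 3))   # filtfilt needs 3x the order
  order <- max(2L, as.integer(order) %/% 2L * 2L)
  b <- signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  ## demean before filtering (kills the DC edge transient exactly) and
  ## after (removes the filter's residual offset)
  dat <- eegData(rec)
  dat <- dat - rowMeans(dat)
  out <- t(apply(dat, 1L, function(x) signal::filtfilt(b, x)))
  out <- out - rowMeans(out)
  EEGRecording(out, fs = fs, labels = channelLabels(rec))
}

#' Re-reference to the mean of named channels
#'
#' Optional hook mirroring linked-mastoid referencing: subtracts the mean
#' of the named channels from every channel. A no-op when `channels` is
#' empty.
#'
#' @param rec an [EEGRecording-class].
#' @param channels labels of the reference channels.
#' @return re-referenced [EEGRecording-class].
#' @export
rereference <- function(rec, channels = character()) {
  stopifnot(is(rec, "EEGRecording"))
  if (!length(channels)) return(rec)
  idx <- match(channels, channelLabels(rec))
  if (anyNA(idx))
    stop("reference channel(s) not found: ",
         paste(channels[is.na(idx)], collapse = ", "))
  ref <- colMeans(eegData(rec)[idx, , drop = FALSE])
  EEGRecording(sweep(eegData(rec), 2L, ref), fs = samplingRate(rec),
               labels = channelLabels(rec))
}

#' Downsample a recording
#'
#' Anti-aliased downsampling to `targetFs`. Integer factors use a zero-phase
#' FIR low-pass at 80 percent of the new Nyquist frequency followed by
#' decimation; non-integer rational factors fall back to
#' [signal::resample()]. Upsampling is refused.
#'
#' @param rec an [EEGRecording-class].
#' @param targetFs target sampling rate in Hz (default 256).
#' @return resampled [EEGRecording-class]; duration preserved within one
#'   sample.
#' @export
resampleTo <- function(rec, targetFs = 256) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (targetFs > fs) stop("upsampling (", fs, " -> ", targetFs, " Hz) is not supported")
  if (targetFs == fs) return(rec)
  dat <- eegData(rec)
  if (abs(fs / targetFs - round(fs / targetFs)) < 1e-9) {
    q <- as.integer(round(fs / targetFs))
    cutoff <- 0.8 * (targetFs / 2)
    order <- max(48L, as.integer(round(20 * q)) %/% 2L * 2L)
    order <- min(order, max(2L, floor((ncol(dat) - 4) / 3) %/% 2L * 2L))
    b <- signal::fir1(order, cutoff / (fs / 2), type = "low")
    out <- t(apply(dat, 1L, function(x) {
      signal::filtfilt(b, x)[seq(1L, length(x), by = q)]
    }))
  } else {
    pq <- rational_approx(targetFs / fs)
    out <- t(apply(dat, 1L, function(x) signal::resample(x, pq[1L], pq[2L])))
  }
  EEGRecording(out, fs = targetFs, labels = channelLabels(rec))
}

rational_approx <- function(x, max_den = 1024L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err < 1e-12) break
  }
  best
}

#' Keep the first minute of a recording
#'
#' @param rec an [EEGRecording-class] of at least 60 s.
#' @param seconds duration to keep (default 60).
#' @return truncated [EEGRecording-class].
#' @export
selectFirstMinute <- function(rec, seconds = 60) {
  stopifnot(is(rec, "EEGRecording"))
  avail <- nSamples(rec) / samplingRate(rec)
  if (avail < seconds - 1e-9)
    stop(sprintf("recording is only %.3f s long; %.0f s required", avail, seconds))
  keep <- as.integer(round(seconds * samplingRate(rec)))
  EEGRecording(eegData(rec)[, seq_len(keep), drop = FALSE],
               fs = samplingRate(rec), labels = channelLabels(rec))
}

#' Split a recording into contiguous fixed-duration windows
#'
#' Non-overlapping windows of `duration` seconds; a trailing remainder
#' shorter than one window is discarded with a message.
#'
#' @param rec an [EEGRecording-class].
#' @param duration window duration in seconds (default 5).
#' @return A [WindowSet-class].
#' @export
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 15360), nrow = 2), fs = 256)
#' windowRecording(rec)
windowRecording <- function(rec, duration = 5) {
  stopifnot(is(rec, "EEGRecording"))
  if (duration <= 0) stop("window duration must be positive")
  L <- as.integer(round(duration * samplingRate(rec)))
  n <- nSamples(rec)
  if (n < L)
    stop(sprintf("recording (%d samples) shorter than one %g s window (%d samples)",
                 n, duration, L))
  k <- n %/% L
  if (n %% L != 0L)
    message(sprintf("discarding trailing %d samples (< one window)", n %% L))
  w <- array(0, dim = c(nChannels(rec), L, k))
  dat <- eegData(rec)
  for (i in seq_len(k)) w[, , i] <- dat[, ((i - 1L) * L + 1L):(i * L)]
  new("WindowSet", windows = w, fs = samplingRate(rec), duration = duration,
      labels = channelLabels(rec))
}
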