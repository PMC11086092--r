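#' EEGRecording: one subject's multichannel EEG signal
#'
#' Container for a channels-by-samples real matrix (microvolts) together with
#' its sampling rate and channel labels. The sampling period in seconds is
#' `1/samplingRate(x)`.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot labels character vector of channel labels, one per row of `data`.
#'
#' @seealso [EEGRecording()] for the user-facing constructor,
#'   [bandpassDC()], [resampleTo()], [windowRecording()].
#' @export
setClass("EEGRecording",
  slots = c(data = "matrix", fs = "numeric", labels = "character")
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be a numeric matrix")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@labels) != nrow(object@data))
    msg <- c(msg, "one label per channel required")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (is.numeric(object@data) && !all(is.finite(object@data))) {
    bad <- which(rowSums(!is.finite(object@data)) > 0L)
    msg <- c(msg, paste0("non-finite samples in channel(s): ",
                         paste(object@labels[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels channel labels; defaults to `Ch1..Chn`.
#' @return An [EEGRecording-class] object.
#' @export
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), nrow = 2), fs = 256)
#' rec
EEGRecording <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels) && !is.null(rownames(data))) labels <- rownames(data)
  dimnames(data) <- NULL
  if (is.null(labels)) labels <- paste0("Ch", seq_len(nrow(data)))
  new("EEGRecording", data = data, fs = as.numeric(fs), labels = as.character(labels))
}

#' WindowSet: contiguous fixed-length windows of a recording
#'
#' @slot windows 3-d array, channels x window-length x n-windows.
#' @slot fs sampling rate in Hz.
#' @slot duration window duration in seconds.
#' @slot labels channel labels.
#' @export
setClass("WindowSet",
  slots = c(windows = "array", fs = "numeric", duration = "numeric",
            labels = "character")
)

setValidity("WindowSet", function(object) {
  d <- dim(object@windows)
  if (length(d) != 3L) return("windows must be a 3-d array")
  if (length(object@labels) != d[1L]) return("one label per channel required")
  if (abs(d[2L] - object@duration * object@fs) > 0.5)
    return("window length inconsistent with duration * fs")
  TRUE
})

#' SubbandWindowSet: per-window, per-channel sub-band series
#'
#' For each 5 s window and channel, holds the five band-limited
#' reconstructions (delta..gamma), each the same length as the window.
#'
#' @slot series 4-d array, channels x window-length x n-windows x 5 bands.
#' @slot fs sampling rate in Hz (must be 256; the band-to-level map is
#'   specific to that rate).
#' @slot labels channel labels.
#' @export
setClass("SubbandWindowSet",
  slots = c(series = "array", fs = "numeric", labels = "character")
)

setValidity("SubbandWindowSet", function(object) {
  d <- dim(object@series)
  if (length(d) != 4L || d[4L] != 5L)
    return("series must be channels x length x windows x 5 bands")
  if (!all(is.finite(object@series))) return("non-finite sub-band series")
  TRUE
})

#' CohortFeatureTable: per-subject aggregated non-linear features
#'
#' Tidy table of window-mean feature values on the
#' (subject, channel, band, feature) grid, plus subject metadata.
#'
#' @slot table data.frame with columns subject, channel, band, feature,
#'   value, nWindows, status.
#' @slot subjects data.frame with columns subject, group, psqi.
#' @export
setClass("CohortFeatureTable",
  slots = c(table = "data.frame", subjects = "data.frame")
)

setValidity("CohortFeatureTable", function(object) {
  need <- c("subject", "channel", "band", "feature", "value", "nWindows", "status")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (!all(c("subject", "group", "psqi") %in% names(object@subjects)))
    return("subjects must have columns subject, group, psqi")
  if (!all(object@table$subject %in% object@subjects$subject))
    return("table contains subjects missing from metadata")
  cnt <- table(object@table[, c("subject", "channel", "band")])
  if (length(cnt) && any(cnt != length(unique(object@table$feature))))
    return("incomplete feature grid")
  TRUE
})

#' AccuracyGrid: LOOCV accuracy per (channel, band, classifier)
#'
#' @slot grid data.frame with columns channel, band, classifier, accuracy
#'   (in 0..1; NA with a reason for failed cells), status.
#' @slot pair character(2), the two group labels compared.
#' @slot nSubjects integer, subjects entering the LOOCV.
#' @slot normalization "pooled" or "foldwise".
#' @export
setClass("AccuracyGrid",
  slots = c(grid = "data.frame", pair = "character", nSubjects = "integer",
            normalization = "character")
)

setValidity("AccuracyGrid", function(object) {
  need <- c("channel", "band", "classifier", "accuracy", "status")
  if (!all(need %in% names(object@grid)))
    return(paste("grid must have columns:", paste(need, collapse = ", ")))
  acc <- object@grid$accuracy
  if (any(!is.na(acc) & (acc < 0 | acc > 1)))
    return("accuracies must lie in [0, 1]")
  if (length(object@pair) != 2L) return("pair must name two groups")
  TRUE
})
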