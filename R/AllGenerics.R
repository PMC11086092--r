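#' @name accessors
#' @title Accessors for pipeline containers
#' @description Slot access for the S4 containers goes through these
#'   accessors; slots are an implementation detail.
#' @param x an object.
#' @return `eegData`: channels x samples matrix. `samplingRate`: Hz.
#'   `samplingPeriod`: seconds. `channelLabels`: character vector.
#'   `nChannels`, `nSamples`, `nWindows`: integers. `featureTable`,
#'   `subjectInfo`, `accuracyTable`: data.frames.
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("samplingPeriod", function(x) standardGeneric("samplingPeriod"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setGeneric("subjectInfo", function(x) standardGeneric("subjectInfo"))
#' @rdname accessors
#' @export
setGeneric("accuracyTable", function(x) standardGeneric("accuracyTable"))

#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingPeriod", "EEGRecording", function(x) 1 / x@fs)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@labels)
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

#' @rdname accessors
setMethod("samplingRate", "WindowSet", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "WindowSet", function(x) x@labels)
#' @rdname accessors
setMethod("nChannels", "WindowSet", function(x) dim(x@windows)[1L])
#' @rdname accessors
setMethod("nWindows", "WindowSet", function(x) dim(x@windows)[3L])

#' @rdname accessors
setMethod("samplingRate", "SubbandWindowSet", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "SubbandWindowSet", function(x) x@labels)
#' @rdname accessors
setMethod("nChannels", "SubbandWindowSet", function(x) dim(x@series)[1L])
#' @rdname accessors
setMethod("nWindows", "SubbandWindowSet", function(x) dim(x@series)[3L])

#' @rdname accessors
setMethod("featureTable", "CohortFeatureTable", function(x) x@table)
#' @rdname accessors
setMethod("subjectInfo", "CohortFeatureTable", function(x) x@subjects)

#' @rdname accessors
setMethod("accuracyTable", "AccuracyGrid", function(x) x@grid)

#' Extract one window as a matrix
#'
#' @param x a [WindowSet-class].
#' @param i window index.
#' @return channels x window-length matrix.
#' @export
setGeneric("getWindow", function(x, i) standardGeneric("getWindow"))

#' @rdname getWindow
setMethod("getWindow", "WindowSet", function(x, i) {
  stopifnot(i >= 1L, i <= nWindows(x))
  w <- x@windows[, , i, drop = FALSE]
  dim(w) <- dim(w)[1:2]
  rownames(w) <- x@labels
  w
})

#' Extract one band series
#'
#' @param x a [SubbandWindowSet-class].
#' @param channel channel index or label.
#' @param window window index.
#' @param band one of `bandNames()`.
#' @return numeric vector of window length.
#' @export
setGeneric("bandSeries", function(x, channel, window, band)
  standardGeneric("bandSeries"))

#' @rdname bandSeries
setMethod("bandSeries", "SubbandWindowSet", function(x, channel, window, band) {
  band <- match.arg(band, BAND_NAMES)
  if (is.character(channel)) channel <- match(channel, x@labels)
  x@series[channel, , window, match(band, BAND_NAMES)]
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nChannels(object), nSamples(object), object@fs,
              nSamples(object) / object@fs))
  cat(" channels:", paste(head(object@labels, 6), collapse = ", "),
      if (nChannels(object) > 6) "..." else "", "\n")
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows of %g s (%d samples) x %d channels @ %g Hz\n",
              nWindows(object), object@duration, dim(object@windows)[2L],
              nChannels(object), object@fs))
})

setMethod("show", "SubbandWindowSet", function(object) {
  cat(sprintf("SubbandWindowSet: %d channels x %d samples x %d windows x 5 bands @ %g Hz\n",
              nChannels(object), dim(object@series)[2L], nWindows(object),
              object@fs))
})

setMethod("show", "CohortFeatureTable", function(object) {
  tb <- object@table
  cat(sprintf("CohortFeatureTable: %d subjects x %d channels x %d bands x %d features\n",
              length(unique(tb$subject)), length(unique(tb$channel)),
              length(unique(tb$band)), length(unique(tb$feature))))
  cat(" groups:", paste(sprintf("%s (n=%d)",
      names(table(object@subjects$group)), table(object@subjects$group)),
      collapse = ", "), "\n")
  nmiss <- sum(is.na(tb$value))
  if (nmiss) cat(" missing cells:", nmiss, "\n")
})

setMethod("show", "AccuracyGrid", function(object) {
  g <- object@grid
  cat(sprintf("AccuracyGrid: %s vs %s (%d subjects, %s z-scoring)\n",
              object@pair[1L], object@pair[2L], object@nSubjects,
              object@normalization))
  cat(sprintf(" %d channels x %d bands x %d classifiers; accuracy range %.2f-%.2f\n",
              length(unique(g$channel)), length(unique(g$band)),
              length(unique(g$classifier)),
              min(g$accuracy, na.rm = TRUE), max(g$accuracy, na.rm = TRUE)))
})
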