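#' Read a multichannel EEG recording
#'
#' Supports 16-bit EDF (European Data Format) and plain delimited text
#' matrices (samples in rows, one column per channel, labels in the header
#' row) with the sampling rate supplied either via `fs` or a JSON sidecar
#' `<path>.json` containing at least `{"fs": <Hz>}`.
#'
#' Data are promoted to double precision. Non-finite samples are rejected
#' with an error naming the offending channel.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"edf"` or `"matrix"`.
#' @param fs sampling rate in Hz for matrix files without a sidecar.
#' @return An [EEGRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = c("auto", "edf", "matrix"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  rec <- if (format == "edf") read_edf(path) else read_matrix(path, fs)
  v <- validObject(rec, test = TRUE)
  if (!isTRUE(v)) stop("invalid recording in ", path, ": ", paste(v, collapse = "; "))
  rec
}

#' Write a multichannel EEG recording
#'
#' The matrix format stores samples as rows with channel labels in the
#' header plus a JSON sidecar carrying the sampling rate; EDF stores 16-bit
#' samples with per-channel physical scaling (quantization error at most
#' one part in 2^16 - 1 of the channel's range).
#'
#' @param rec an [EEGRecording-class].
#' @param path output file.
#' @param format `"matrix"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  stopifnot(is(rec, "EEGRecording"))
  if (format == "matrix") {
    m <- t(eegData(rec))
    colnames(m) <- channelLabels(rec)
    write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(fs = samplingRate(rec),
                              labels = channelLabels(rec)),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

read_matrix <- function(path, fs = NULL) {
  if (is.null(fs)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("matrix format needs a sampling rate: pass fs= or provide ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("sidecar ", sidecar, " lacks an fs entry")
    fs <- meta$fs
  }
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  storage.mode(m) <- "double"
  bad <- colSums(!is.finite(m)) > 0L
  if (any(bad))
    stop("non-finite samples in ", path, ", channel(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  EEGRecording(t(m), fs = fs, labels = colnames(m))
}

## --- minimal EDF (16-bit) reader/writer -------------------------------

## Render a physical min/max into at most 8 ASCII characters, keeping as
## many significant digits as fit.
phys_str <- function(x) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= 8L) return(s)
  }
  s
}

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

write_edf <- function(rec, path) {
  dat <- eegData(rec)
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(dat)
  nrec <- ncol(dat) %/% fs
  if (nrec * fs != ncol(dat))
    stop("EDF export requires a whole number of 1 s records")
  pmin_ <- apply(dat, 1L, min); pmax_ <- apply(dat, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  ## widen slightly, render into the 8-char header field, and reuse the
  ## *parsed* header values for scaling so truncation cannot corrupt it
  rng <- pmax_ - pmin_
  pmin_s <- vapply(pmin_ - 0.01 * rng, phys_str, "")
  pmax_s <- vapply(pmax_ + 0.01 * rng, phys_str, "")
  pmin_ <- as.numeric(pmin_s); pmax_ <- as.numeric(pmax_s)
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic subject", 80),
                pad("eegcomplexity export", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(256L * (1L + nch), 8), pad("", 44),
                pad(nrec, 8), pad(1L, 8), pad(nch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(channelLabels(rec), 16), list(rep("", nch), 80),
    list(rep("uV", nch), 8),
    list(pmin_s, 8),
    list(pmax_s, 8),
    list(rep(dmin, nch), 8), list(rep(dmax, nch), 8),
    list(rep("", nch), 80), list(rep(fs, nch), 8), list(rep("", nch), 32))
  for (f in fields)
    writeChar(paste(vapply(f[[1L]], pad, "", width = f[[2L]]), collapse = ""),
              con, eos = NULL)
  scale_ <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- as.integer(round((dat[ch, idx] - pmin_[ch]) * scale_[ch]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nb) trimws(readChar(con, nb, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  per <- function(nb) vapply(seq_len(nch), function(i) rd(nb), "")
  labels <- per(16); per(80); per(8)
  pmin_ <- as.numeric(per(8)); pmax_ <- as.numeric(per(8))
  dmin <- as.numeric(per(8)); dmax <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8)); per(32)
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates is not supported: ", path)
  fs <- spr[1L] / recdur
  dat <- matrix(0, nrow = nch, ncol = nrec * spr[1L])
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[1L], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[1L])
        stop("truncated EDF record in ", path, ", channel ", labels[ch])
      idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
      dat[ch, idx] <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch]) + pmin_[ch]
    }
  }
  EEGRecording(dat, fs = fs, labels = labels)
}
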