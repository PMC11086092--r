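#' LOOCV accuracy grid for one group pair
#'
#' For every (channel, band) cell, runs leave-one-out cross-validation of
#' each classifier preset on that cell's ten z-scored features.
#'
#' With `normalization = "pooled"` the cell is z-scored once over both
#' groups (the published pipeline order); this uses all subjects before
#' cross-validation and therefore leaks pooled distributional information
#' into the folds. `"foldwise"` recomputes the z statistics from each
#' training fold only and applies them to the held-out subject, which is
#' leakage-free. Missing feature values are mean-imputed within group
#' (imputation counts are recorded in the grid's `status`).
#'
#' @param table an aggregated [CohortFeatureTable-class] (unnormalized;
#'   pooled z-scoring is applied internally).
#' @param pair a [groupPair()].
#' @param specs classifier presets (default: all sixteen).
#' @param normalization `"pooled"` (default, mirrors the published method)
#'   or `"foldwise"`.
#' @param verbose print one line per channel.
#' @return an [AccuracyGrid-class].
#' @seealso [summarizeGrid()], [scalpMap()]
#' @export
runPair <- function(table, pair, specs = classifierSpecs(),
                    normalization = c("pooled", "foldwise"),
                    verbose = FALSE) {
  stopifnot(is(table, "CohortFeatureTable"))
  normalization <- match.arg(normalization)
  subj <- c(pair$subjectsA, pair$subjectsB)
  y <- factor(rep(pair$groups, c(length(pair$subjectsA),
                                 length(pair$subjectsB))),
              levels = pair$groups)
  tb <- featureTable(table)
  tb <- tb[tb$subject %in% subj, ]
  channels <- sort(unique(tb$channel))
  bands <- intersect(BAND_NAMES, unique(tb$band))
  feats <- featureNames()

  rows <- list()
  for (ch in channels) {
    for (b in bands) {
      cell <- tb[tb$channel == ch & tb$band == b, ]
      X <- matrix(NA_real_, nrow = length(subj), ncol = length(feats),
                  dimnames = list(subj, feats))
      idx <- cbind(match(cell$subject, subj), match(cell$feature, feats))
      X[idx] <- cell$value
      imputed <- impute_within_group(X, y)
      for (spec in specs) {
        acc <- tryCatch({
          if (normalization == "pooled")
            loocv(zscore_cols(imputed$X), y, spec)
          else
            loocv_foldwise(imputed$X, y, spec)
        }, error = function(e) structure(NA_real_, reason = conditionMessage(e)))
        status <- if (is.na(acc)) paste0("failed: ", attr(acc, "reason"))
                  else if (imputed$n > 0L) sprintf("ok (%d imputed)", imputed$n)
                  else "ok"
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, band = b, classifier = spec$name,
          accuracy = as.numeric(acc), status = status)
      }
    }
    if (verbose) message("classified channel ", ch)
  }
  grid <- do.call(rbind, rows)
  grid$band <- factor(grid$band, levels = BAND_NAMES)
  new("AccuracyGrid", grid = grid, pair = pair$groups,
      nSubjects = length(subj), normalization = normalization)
}

impute_within_group <- function(X, y) {
  n <- 0L
  for (g in levels(y)) {
    rows <- which(y == g)
    for (j in seq_len(ncol(X))) {
      miss <- rows[is.na(X[rows, j])]
      if (length(miss)) {
        fill <- mean(X[rows, j], na.rm = TRUE)
        if (!is.finite(fill)) fill <- mean(X[, j], na.rm = TRUE)
        if (!is.finite(fill)) fill <- 0
        X[miss, j] <- fill
        n <- n + length(miss)
      }
    }
  }
  list(X = X, n = n)
}

zscore_cols <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2L, sd)
  sg[sg == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sg, "/")
}

## LOOCV where the z statistics come from the training fold only.
loocv_foldwise <- function(X, y, spec) {
  n <- nrow(X)
  if (nlevels(droplevels(y)) < 2L) stop("LOOCV needs both classes present")
  trainer <- buildClassifier(spec)
  correct <- 0L
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sg <- apply(tr, 2L, sd)
    sg[sg == 0] <- 1
    trz <- sweep(sweep(tr, 2L, mu), 2L, sg, "/")
    tez <- sweep(sweep(X[i, , drop = FALSE], 2L, mu), 2L, sg, "/")
    model <- trainer(trz, droplevels(y[-i]))
    correct <- correct +
      as.integer(as.character(model$predict(tez)) == as.character(y[i]))
  }
  correct / n
}

#' Summarize an accuracy grid per band and pick the best classifier
#'
#' Per (classifier, band): the mean and the maximum accuracy over
#' channels. The best classifier maximizes the grand mean accuracy over
#' all cells; ties break lexicographically by preset name with a message.
#'
#' @param grid an [AccuracyGrid-class].
#' @return list with `bandSummary` (classifier, band, mean, max),
#'   `best` (preset name), `bestBandTable` (rows Mean/Max, one column per
#'   band, for the best classifier) and `tied` (logical).
#' @export
summarizeGrid <- function(grid) {
  stopifnot(is(grid, "AccuracyGrid"))
  g <- accuracyTable(grid)
  g <- g[!is.na(g$accuracy), ]
  if (!nrow(g)) stop("empty accuracy grid")
  mean_ <- aggregate(accuracy ~ classifier + band, g, mean)
  max_ <- aggregate(accuracy ~ classifier + band, g, max)
  bandSummary <- merge(mean_, max_, by = c("classifier", "band"),
                       suffixes = c(".mean", ".max"))
  names(bandSummary)[3:4] <- c("mean", "max")
  grand <- aggregate(accuracy ~ classifier, g, mean)
  top <- max(grand$accuracy)
  cands <- sort(grand$classifier[abs(grand$accuracy - top) < 1e-12])
  tied <- length(cands) > 1L
  if (tied)
    message("best-classifier tie between: ", paste(cands, collapse = ", "),
            "; reporting the first by name")
  best <- cands[1L]
  bs <- bandSummary[bandSummary$classifier == best, ]
  bands <- intersect(BAND_NAMES, as.character(bs$band))
  btab <- rbind(Mean = setNames(bs$mean[match(bands, bs$band)], bands),
                Max = setNames(bs$max[match(bands, bs$band)], bands))
  list(bandSummary = bandSummary[order(bandSummary$classifier,
                                       bandSummary$band), ],
       best = best, bestBandTable = btab, tied = tied)
}

#' Permutation null band for per-channel LOOCV accuracies
#'
#' Estimates the null distribution of a classifier's per-channel LOOCV
#' accuracy by permuting the group labels of the pair's subjects:
#' `nPerm` label permutations are evaluated at every (channel, `band`)
#' cell and the pooled accuracies give the band's quantiles. LOOCV
#' accuracies are not binomial (folds are correlated and flexible
#' classifiers overfit pooled z-scored features), so this simulated band
#' is the appropriate reference for judging whether an observed accuracy
#' is compatible with chance. The returned band is simultaneous across
#' `nChannelsTested` channels (Sidak-adjusted per-channel level).
#'
#' @param table aggregated [CohortFeatureTable-class] (unnormalized).
#' @param pair a [groupPair()].
#' @param spec a single [classifierSpec()].
#' @param band sub-band to examine (default "theta").
#' @param nPerm number of label permutations (default 60).
#' @param level simultaneous coverage (default 0.95).
#' @param nChannelsTested channels the band must cover jointly (default:
#'   all channels used).
#' @param channels optional subset of channels whose cells feed the
#'   permutation distribution (e.g. only channels without injected
#'   effects, whose features are exchangeable under the null).
#' @param seed RNG seed for the permutations.
#' @return list with `lo`, `hi` (the band) and `accuracies` (the pooled
#'   permutation accuracies).
#' @export
nullAccuracyBand <- function(table, pair, spec, band = "theta", nPerm = 60L,
                             level = 0.95, nChannelsTested = NULL,
                             channels = NULL, seed = 1L) {
  stopifnot(is(table, "CohortFeatureTable"))
  band <- match.arg(band, BAND_NAMES)
  subj <- c(pair$subjectsA, pair$subjectsB)
  y <- factor(rep(pair$groups, c(length(pair$subjectsA),
                                 length(pair$subjectsB))),
              levels = pair$groups)
  tb <- featureTable(table)
  tb <- tb[tb$subject %in% subj & tb$band == band, ]
  if (is.null(channels)) channels <- sort(unique(tb$channel))
  if (is.null(nChannelsTested)) nChannelsTested <- length(channels)
  feats <- featureNames()
  cellX <- lapply(channels, function(ch) {
    cell <- tb[tb$channel == ch, ]
    X <- matrix(NA_real_, nrow = length(subj), ncol = length(feats),
                dimnames = list(subj, feats))
    X[cbind(match(cell$subject, subj), match(cell$feature, feats))] <-
      cell$value
    zscore_cols(impute_within_group(X, y)$X)
  })
  accs <- with_seed(seed, {
    vapply(seq_len(nPerm), function(b) {
      yp <- sample(y)
      vapply(cellX, function(X) loocv(X, yp, spec), numeric(1))
    }, numeric(length(cellX)))
  })
  alpha <- 1 - level^(1 / max(1L, nChannelsTested))
  qs <- quantile(accs, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                 type = 1)
  list(lo = qs[1L], hi = qs[2L], accuracies = as.numeric(accs))
}

#' Schematic scalp map of per-channel accuracies
#'
#' Inverse-distance-weighted interpolation of one band's accuracies for
#' one classifier over 2-D electrode coordinates, drawn with the graphics
#' device (written to `file` as PNG when given). Channels without
#' coordinates trigger a labeled bar-chart fallback. Purely
#' presentational.
#'
#' @param grid an [AccuracyGrid-class].
#' @param coords data.frame with columns `label`, `x`, `y` (unit-disk
#'   scalp coordinates), or `NULL` to force the bar chart.
#' @param band one of `bandNames()`.
#' @param classifier preset name; default: best by [summarizeGrid()].
#' @param file optional PNG path.
#' @return invisibly, the interpolated matrix (or the accuracy vector for
#'   the fallback).
#' @export
scalpMap <- function(grid, coords = NULL, band = "delta", classifier = NULL,
                     file = NULL) {
  stopifnot(is(grid, "AccuracyGrid"))
  band <- match.arg(band, BAND_NAMES)
  if (is.null(classifier)) classifier <- summarizeGrid(grid)$best
  g <- accuracyTable(grid)
  g <- g[g$band == band & g$classifier == classifier & !is.na(g$accuracy), ]
  if (!nrow(g)) stop("no accuracies for band ", band, " / ", classifier)
  acc <- setNames(g$accuracy, g$channel)
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  ok <- !is.null(coords) &&
    all(c("label", "x", "y") %in% names(coords)) &&
    all(names(acc) %in% coords$label)
  if (!ok) {
    if (!is.null(coords)) warning("missing electrode coordinates; ",
                                  "falling back to a bar chart")
    graphics::barplot(acc, las = 2, ylim = c(0, 1),
                      ylab = "LOOCV accuracy",
                      main = sprintf("%s / %s", classifier, band))
    return(invisible(acc))
  }
  xy <- coords[match(names(acc), coords$label), ]
  gx <- seq(-1.05, 1.05, length.out = 80)
  gy <- gx
  zmat <- matrix(NA_real_, 80, 80)
  for (i in seq_along(gx)) for (j in seq_along(gy)) {
    if (gx[i]^2 + gy[j]^2 > 1.1) next
    d2 <- (xy$x - gx[i])^2 + (xy$y - gy[j])^2
    w <- 1 / pmax(d2, 1e-9)
    zmat[i, j] <- sum(w * acc) / sum(w)
  }
  graphics::image(gx, gy, zmat, asp = 1, axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "",
                  main = sprintf("%s / %s", classifier, band))
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
  graphics::points(xy$x, xy$y, pch = 21, bg = "white")
  graphics::text(xy$x, xy$y, labels = names(acc), pos = 3, cex = 0.6)
  invisible(zmat)
}

#' Schematic coordinates for a default 32-channel layout
#'
#' A synthetic, evenly spaced spiral layout on the unit disk for channels
#' named `Ch1..ChN`; a stand-in for a real montage, sufficient for the
#' presentational scalp map.
#'
#' @param n number of channels.
#' @return data.frame with columns label, x, y.
#' @export
defaultScalpCoords <- function(n = 32L) {
  i <- seq_len(n)
  r <- 0.95 * sqrt((i - 0.5) / n)
  th <- i * pi * (3 - sqrt(5))
  data.frame(label = paste0("Ch", i), x = r * cos(th), y = r * sin(th))
}
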