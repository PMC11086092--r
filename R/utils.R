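# Internal helpers.

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed derivation, kept below 2^31.
sub_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed)
  for (i in ix) s <- (s * 69069 + i) %% 2147483647
  as.integer(s)
}

## Slope of the ordinary least-squares fit of y on x.
ls_slope <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(NA_real_)
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

## Longest contiguous low-curvature sub-range of a log-log curve:
## local slopes between consecutive grid points must stay within
## `tol` (relative) of the window median. Returns index range (start, end)
## into x/y, spanning at least `min_len` points, or NULL if none exists.
scaling_region <- function(x, y, tol = 0.15, min_len = 5L) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < min_len) return(NULL)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  s <- diff(y) / diff(x)
  best <- NULL
  for (i in seq_len(n - min_len + 1L)) {
    for (j in seq(i + min_len - 2L, n - 1L)) {
      w <- s[i:j]
      med <- median(w)
      ok <- if (abs(med) < 1e-12) all(abs(w) < 1e-12)
            else all(abs(w - med) <= tol * abs(med))
      if (ok) {
        if (is.null(best) || (j - i) > (best[2L] - best[1L])) best <- c(i, j + 1L)
      } else break
    }
  }
  if (is.null(best)) return(NULL)
  list(idx = best[1L]:best[2L], which_kept = which(keep))
}

## Fit slope over the automatically selected scaling region; falls back to
## the full range (flagged) when no region qualifies.
region_slope <- function(x, y, tol = 0.15, min_len = 5L) {
  reg <- scaling_region(x, y, tol = tol, min_len = min_len)
  if (is.null(reg))
    return(list(slope = ls_slope(x, y), reliable = FALSE))
  idx <- reg$which_kept[reg$idx]
  list(slope = ls_slope(x[idx], y[idx]), reliable = TRUE)
}
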