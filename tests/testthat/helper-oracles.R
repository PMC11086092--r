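# Brute-force reference implementations, written independently of the
# package internals and kept deliberately naive (double loops).

naive_corr_integral <- function(X, rgrid, theiler) {
  M <- nrow(X)
  counts <- numeric(length(rgrid))
  npairs <- 0
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (j <= i + theiler) next
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      npairs <- npairs + 1
      counts <- counts + as.numeric(d <= rgrid)
    }
  }
  counts / npairs
}

naive_rs <- function(x, sizes) {
  vapply(sizes, function(n) {
    k <- length(x) %/% n
    vals <- c()
    for (i in seq_len(k)) {
      seg <- x[((i - 1) * n + 1):(i * n)]
      if (sd(seg) == 0) next
      y <- cumsum(seg - mean(seg))
      vals <- c(vals, (max(y) - min(y)) / sd(seg))
    }
    mean(vals)
  }, numeric(1))
}

naive_dfa_F <- function(x, ms) {
  N <- length(x)
  y <- cumsum(x - mean(x))
  vapply(ms, function(m) {
    k <- N %/% m
    tot <- 0
    for (i in seq_len(k)) {
      seg <- y[((i - 1) * m + 1):(i * m)]
      t <- seq_len(m)
      fit <- lm(seg ~ t)
      tot <- tot + sum(residuals(fit)^2)
    }
    sqrt(tot / (k * m))
  }, numeric(1))
}

naive_higuchi_L <- function(x, kmax) {
  N <- length(x)
  vapply(seq_len(kmax), function(k) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, N, by = k)
      a <- length(idx) - 1
      s <- 0
      for (i in 2:length(idx)) s <- s + abs(x[idx[i]] - x[idx[i - 1]])
      Lm[m] <- s * (N - 1) / (a * k)
    }
    mean(Lm) / k
  }, numeric(1))
}

naive_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    n <- N - mm + 1
    lc <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      lc[i] <- log(cnt / n)
    }
    mean(lc)
  }
  phi(m) - phi(m + 1)
}

naive_katz <- function(x) {
  N <- length(x)
  L <- sum(sqrt(1 + diff(x)^2))
  a <- L / (N - 1)
  d <- max(sqrt(((2:N) - 1)^2 + (x[2:N] - x[1])^2))
  log(L / a) / log(d / a)
}

## periodogram-based fraction of spectral power inside a frequency band
power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (0:(n - 1)) / n * fs
  keep <- f <= fs / 2
  sel <- f >= lo & f <= hi
  sum(p[keep & sel]) / sum(p[keep])
}

dominant_frequency <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (0:(n - 1)) / n * fs
  keep <- f > 0 & f <= fs / 2
  f[keep][which.max(p[keep])]
}
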