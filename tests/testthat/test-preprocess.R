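make_rec <- function(nch = 2, n = 2560, fs = 256, seed = 1) {
  set.seed(seed)
  EEGRecording(matrix(rnorm(nch * n), nrow = nch), fs = fs)
}

test_that("matrix round trip preserves data; NaN loads fail with channel name", {
  rec <- make_rec()
  path <- withr::local_tempfile(fileext = ".txt")
  writeRecording(rec, path, format = "matrix")
  back <- readRecording(path)
  expect_equal(eegData(back), eegData(rec), tolerance = 1e-10)
  expect_identical(channelLabels(back), channelLabels(rec))
  expect_equal(samplingRate(back), 256)

  bad <- eegData(rec)
  bad[2, 5] <- NaN
  m <- t(bad); colnames(m) <- channelLabels(rec)
  path2 <- withr::local_tempfile(fileext = ".txt")
  write.table(m, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readRecording(path2, fs = 256), "Ch2")
})

test_that("EDF round trip is exact to the 16-bit quantization", {
  set.seed(2)
  rec <- EEGRecording(matrix(rnorm(32 * 256 * 60, sd = 20), nrow = 32),
                      fs = 256)
  path <- withr::local_tempfile(fileext = ".edf")
  writeRecording(rec, path, format = "edf")
  back <- readRecording(path)
  expect_identical(dim(eegData(back)), c(32L, 15360L))
  rng <- apply(eegData(rec), 1, function(x) diff(range(x)))
  quant <- 1.1 * rng / (2^16 - 1)   # slightly widened physical range
  err <- apply(abs(eegData(back) - eegData(rec)), 1, max)
  expect_true(all(err <= quant))
})

test_that("band-pass removes 50 Hz and DC, keeps 10 Hz, and is linear", {
  fs <- 256; t <- seq_len(fs * 10) / fs
  mk <- function(x) EEGRecording(matrix(x, nrow = 1), fs = fs)
  out50 <- eegData(bandpassDC(mk(sin(2 * pi * 50 * t))))[1, ]
  expect_lt(sqrt(mean(out50^2)) / sqrt(0.5), 0.10)
  out10 <- eegData(bandpassDC(mk(sin(2 * pi * 10 * t))))[1, ]
  mid <- seq(fs, length(t) - fs)   # ignore edge transients
  expect_lt(abs(sqrt(mean(out10[mid]^2)) / sqrt(0.5) - 1), 0.05)
  outdc <- eegData(bandpassDC(mk(rep(3, length(t)))))[1, ]
  expect_lt(max(abs(outdc)), 1e-9 * 3)
  expect_error(bandpassDC(mk(sin(t)), hi = 130), "Nyquist")
  ## linearity
  set.seed(3)
  x <- rnorm(fs * 5)
  f1 <- eegData(bandpassDC(mk(3 * x)))[1, ]
  f2 <- 3 * eegData(bandpassDC(mk(x)))[1, ]
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("re-referencing subtracts the mean of the named channels", {
  rec <- make_rec(nch = 3)
  rr <- rereference(rec, c("Ch1", "Ch2"))
  ref <- colMeans(eegData(rec)[1:2, ])
  expect_equal(eegData(rr)[3, ], eegData(rec)[3, ] - ref)
  expect_identical(rereference(rec), rec)  # no-op hook
  expect_error(rereference(rec, "M1"), "not found")
})

test_that("resampling: 2048 to 256 Hz geometry and tone fidelity", {
  fs <- 2048; dur <- 12
  t <- seq_len(fs * dur) / fs
  rec <- EEGRecording(matrix(sin(2 * pi * 5 * t), nrow = 1), fs = fs)
  down <- resampleTo(rec, 256)
  expect_equal(samplingRate(down), 256)
  expect_identical(nSamples(down), as.integer(256 * dur))
  ## 5 Hz sine survives with amplitude within 1%
  y <- eegData(down)[1, ]
  mid <- seq(256, length(y) - 256)
  expect_lt(abs(sqrt(mean(y[mid]^2)) / sqrt(0.5) - 1), 0.01)
  expect_identical(resampleTo(rec, fs), rec)
  expect_error(resampleTo(rec, 4096), "upsampling")
})

test_that("first-minute selection truncates or refuses", {
  fs <- 64
  long <- EEGRecording(matrix(rnorm(fs * 300), nrow = 1), fs = fs)
  first <- selectFirstMinute(long)
  expect_identical(nSamples(first), as.integer(60 * fs))
  expect_equal(eegData(first)[1, ], eegData(long)[1, seq_len(60 * fs)])
  exact <- EEGRecording(matrix(rnorm(fs * 60), nrow = 1), fs = fs)
  expect_equal(eegData(selectFirstMinute(exact)), eegData(exact))
  short <- EEGRecording(matrix(rnorm(fs * 59), nrow = 1), fs = fs)
  expect_error(selectFirstMinute(short), "59")
})

test_that("windowing: counts, truncation notice, reassembly, errors", {
  rec <- make_rec(nch = 2, n = 15360)
  ws <- windowRecording(rec, 5)
  expect_identical(nWindows(ws), 12L)
  expect_identical(dim(ws@windows), c(2L, 1280L, 12L))
  ## concatenating the windows reproduces the signal exactly
  expect_identical(
    unname(do.call(cbind, lapply(1:12, function(i) getWindow(ws, i)))),
    unname(eegData(rec)))
  rec62 <- make_rec(nch = 1, n = 62 * 256)
  expect_message(ws62 <- windowRecording(rec62, 5), "discarding")
  expect_identical(nWindows(ws62), 12L)
  expect_error(windowRecording(make_rec(n = 1024), 5), "shorter than one")
  expect_error(windowRecording(rec, -1), "positive")
})
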