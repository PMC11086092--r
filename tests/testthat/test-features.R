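test_that("delay estimation: quarter period for a sine, 1 for i.i.d. noise", {
  sine <- sin(2 * pi * seq_len(1000) / 20)
  expect_identical(estimateDelay(sine), 5L)
  set.seed(10)
  taus <- vapply(1:5, function(i) estimateDelay(rnorm(1024)), integer(1))
  expect_true(all(taus == 1L))
  expect_error(estimateDelay(rep(1, 500)), "degenerate")
  expect_error(estimateDelay(rnorm(32)), "too short")
})

test_that("dimension estimation: closed curve, Lorenz, and noise cap", {
  sine <- sin(2 * pi * seq_len(2000) / 40)
  expect_identical(as.integer(estimateDimension(sine, 10)), 2L)
  lor <- genChaotic("lorenz", 10000, params = list(dt = 0.01), seed = 1)
  m <- suppressWarnings(estimateDimension(lor, estimateDelay(lor)))
  expect_true(m %in% 3:5)
  set.seed(11)
  expect_warning(mN <- estimateDimension(rnorm(2000), 1), "never fell")
  expect_identical(as.integer(mN), 10L)
})

test_that("time-delay embedding obeys M = N - (m-1) tau", {
  att <- embedSeries(1:10, tau = 2, m = 3)
  expect_identical(dim(unclass(att)), c(6L, 3L))
  expect_identical(att[1, ], c(1, 3, 5))
  expect_identical(att[6, ], c(6, 8, 10))
  ident <- embedSeries(sin(1:5), tau = 1, m = 1)
  expect_equal(as.numeric(ident), sin(1:5))
  expect_error(embedSeries(1:5, tau = 3, m = 3), "M = ")
})

test_that("correlation dimension: line segment is one-dimensional", {
  att <- embedSeries(seq(0, 1, length.out = 2000), tau = 1, m = 2)
  d2 <- correlationDimension(att)
  expect_lt(abs(d2 - 1), 0.1)
  expect_error(correlationDimension(embedSeries(rep(1, 300), 1, 2)),
               "degenerate")
  expect_error(correlationDimension(embedSeries(rnorm(50), 1, 2)),
               "at least 100")
})

test_that("largest Lyapunov exponent: chaotic map versus periodic orbit", {
  lg <- genChaotic("logistic", 5000, params = list(r = 4, x0 = 0.2))
  lle <- largestLyapunov(embedSeries(lg, 1, 1), Ts = 1)
  expect_lt(abs(lle - log(2)) / log(2), 0.1)
  sine <- sin(2 * pi * seq_len(3000) / 40)
  lls <- largestLyapunov(embedSeries(sine, 10, 2), Ts = 1)
  expect_lte(lls, 0.05)
  expect_error(largestLyapunov(embedSeries(rnorm(50), 1, 1), Ts = 1),
               "at least 200")
})

test_that("approximate entropy: conventions and regularity ordering", {
  expect_identical(approximateEntropy(rep(2, 200)), 0)
  set.seed(12)
  noise <- rnorm(1024)
  sine <- sin(2 * pi * 6 * seq_len(1024) / 256)
  expect_gt(approximateEntropy(noise), approximateEntropy(sine))
  x <- sine + rnorm(1024, sd = 0.2)
  expect_lt(abs(approximateEntropy(x) - approximateEntropy(10 * x)), 1e-12)
  expect_error(approximateEntropy(rnorm(50)), "too short")
})

test_that("R/S Hurst estimate: null behaviour and degenerate input", {
  set.seed(13)
  est <- vapply(1:10, function(i) as.numeric(hurstRS(rnorm(2048))),
                numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
  expect_error(hurstRS(rep(1, 512)), "degenerate")
  expect_error(hurstRS(rnorm(100)), "too short")
})

test_that("DFA exponent: error handling (nulls are covered at acceptance)", {
  expect_error(dfa(rep(1, 512)), "degenerate")
  expect_error(dfa(rnorm(100)), "too short")
})

test_that("Higuchi fractal dimension: line, noise, smooth bound", {
  expect_lt(abs(higuchiFD(seq(0, 1, length.out = 1024)) - 1), 0.05)
  set.seed(14)
  expect_lt(abs(higuchiFD(rnorm(4096)) - 2), 0.1)
  expect_lte(higuchiFD(sin(2 * pi * 6 * seq_len(1280) / 256)), 1.1)
  expect_error(higuchiFD(rnorm(512), kmax = 1), "kmax")
  expect_error(higuchiFD(rnorm(50)), "too short")
})

test_that("Katz fractal dimension matches direct evaluation", {
  expect_equal(katzFD(seq(2, 12, by = 0.5)), 1, tolerance = 1e-12)  # line
  x <- c(0, 1, 0, 1, 0)
  expect_equal(katzFD(x), naive_katz(x), tolerance = 1e-14)
  expect_gte(katzFD(x), 1)
  expect_error(katzFD(rep(3, 10)), "degenerate")
})

test_that("energy and entropies follow the printed conventions", {
  expect_identical(signalEnergy(c(1, 2, 2)), 9)
  set.seed(15)
  x <- rnorm(100)
  expect_equal(signalEnergy(3 * x), 9 * signalEnergy(x))
  expect_identical(signalEnergy(numeric(64)), 0)
  expect_equal(shannonEntropy(c(1, 1)), 0)
  expect_equal(logEnergyEntropy(c(1, 1)), 0)
  expect_equal(shannonEntropy(0.5), -0.25 * log(0.25))
  expect_equal(logEnergyEntropy(sqrt(exp(1))), -1)
  ## zero samples: no contribution to ETs, floored logarithm in ETL
  expect_equal(shannonEntropy(c(0, 0.5)), -0.25 * log(0.25))
  expect_equal(logEnergyEntropy(c(0, 1)), -log(1e-12))
})

test_that("extractFeatures: full vector, flags, and determinism", {
  x <- genBandOscillation("alpha", 256, 1280, seed = 20) +
    0.3 * genFGN(0.6, 1280, seed = 21)
  f1 <- extractFeatures(x, 256)
  f2 <- extractFeatures(x, 256)
  expect_identical(f1, f2)
  expect_named(f1$values, featureNames())
  expect_true(all(is.finite(f1$values)))

  fc <- extractFeatures(rep(0, 1280), 256)
  expect_identical(fc$values[["EN"]], 0)
  expect_identical(fc$values[["ApEn"]], 0)
  expect_true(all(fc$status[c("D2", "LLE", "H", "DFA", "FDh", "FDk")] ==
                    "degenerate"))

  ## alpha-only subject: alpha-band energy dominates delta by 10x
  rec <- EEGRecording(matrix(genBandOscillation("alpha", 256, 15360,
                                                seed = 22), nrow = 1),
                      fs = 256)
  sbs <- decomposeToSubbands(windowRecording(rec))
  en <- function(b) extractFeatures(bandSeries(sbs, 1, 1, b), 256)$values[["EN"]]
  expect_gt(en("alpha"), 10 * en("delta"))
})
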