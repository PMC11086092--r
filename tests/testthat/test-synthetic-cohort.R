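test_that("fGn generator: white-noise limit, domain errors, determinism", {
  x <- genFGN(0.5, 1024, seed = 1)
  r1 <- acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.1)          # H = 0.5 is memoryless
  expect_equal(genFGN(0.8, 512, seed = 7), genFGN(0.8, 512, seed = 7))
  expect_error(genFGN(1.2, 100), "hurst")
  expect_error(genFGN(0, 100), "hurst")
  expect_error(genFGN(0.5, 1), "n must be")
})

test_that("fGn self-similarity recovered by an independent R/S oracle", {
  skip_if_not_installed("pracma")
  est <- vapply(1:20, function(s) {
    x <- genFGN(0.8, 4096, seed = 1000 + s)
    unname(pracma::hurstexp(x, display = FALSE)$Hrs)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.1)
})

test_that("logistic map: exact iterates, fixed point, parameter errors", {
  x <- genChaotic("logistic", 100, params = list(r = 4, x0 = 0.2),
                  transient = 0)
  expect_equal(x[1:4], c(0.2, 0.64, 0.9216, 0.28901376))
  xf <- genChaotic("logistic", 100, params = list(r = 2, x0 = 0.3))
  expect_equal(tail(xf, 1), 0.5, tolerance = 1e-10)  # fixed point 1 - 1/r
  expect_error(genChaotic("henon", 100), "unknown system")
  expect_error(genChaotic("logistic", 100, params = list(r = 5)), "r must")
  expect_error(genChaotic("logistic", 50), "n must be")
})

test_that("Lorenz trajectory stays on the attractor (bounded)", {
  x <- genChaotic("lorenz", 2000, params = list(dt = 0.01), seed = 2)
  expect_true(all(is.finite(x)))
  expect_lt(max(abs(x)), 25)
  expect_gt(sd(x), 1)  # not collapsed onto a fixed point
})

test_that("band oscillations are spectrally confined", {
  for (b in bandNames()) {
    x <- genBandOscillation(b, fs = 256, n = 1280, seed = 3)
    rng <- bandRange(b)
    expect_gte(power_fraction(x, 256, rng[1], rng[2]), 0.9)
    fd <- dominant_frequency(x, 256)
    expect_gte(fd, rng[1]); expect_lte(fd, rng[2])
  }
  expect_identical(genBandOscillation("delta", 256, 1280, amplitude = 0),
                   numeric(1280))
  expect_error(genBandOscillation("mu", 256, 1280), "unknown band")
})

test_that("cohort bookkeeping: shapes, labels, pseudo-PSQI consistency", {
  cfg <- cohortConfig(c(3, 4), nChannels = 5, duration = 10, seed = 5)
  coh <- genCohort(cfg)
  expect_length(coh$recordings, 7)
  for (rec in coh$recordings) {
    expect_s4_class(rec, "EEGRecording")
    expect_identical(dim(eegData(rec)), c(5L, 2560L))
  }
  expect_identical(coh$subjects$group, rep(c("YG", "OB"), c(3, 4)))
  good <- coh$subjects$group == "YG"
  expect_true(all(coh$subjects$psqi[good] <= 5))
  expect_true(all(coh$subjects$psqi[!good] > 5))
  expect_error(
    cohortConfig(c(2, 2), effects = data.frame(channel = 40, band = "theta",
                                               family = "hurst",
                                               magnitude = 0.1)),
    "channel index")
  expect_error(
    cohortConfig(c(2, 2), effects = data.frame(channel = 1, band = "mu",
                                               family = "hurst",
                                               magnitude = 0.1)),
    "unknown effect band")
})

test_that("cohorts are bit-identical under the same config and seed", {
  cfg <- cohortConfig(c(2, 2), nChannels = 2, duration = 10, seed = 17)
  a <- genCohort(cfg)
  b <- genCohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohortConfig(c(2, 2), nChannels = 2, duration = 10, seed = 18)
  expect_false(identical(genCohort(cfg2), a))
})

test_that("injected hurst effect is local to the targeted cell", {
  fx <- effect_cohort_features()
  tb <- featureTable(fx$cft)
  grp <- fx$subjects$group[match(tb$subject, fx$subjects$subject)]
  rel_shift <- function(ch, band, feat) {
    v <- tb[tb$channel == ch & tb$band == band & tb$feature == feat, ]
    g <- grp[tb$channel == ch & tb$band == band & tb$feature == feat]
    m <- tapply(v$value, g, mean)
    abs(diff(m)) / abs(mean(v$value))
  }
  ## the energy consequence of the hurst shift appears at the target cell...
  expect_gt(rel_shift("Ch1", "theta", "EN"), 0.15)
  ## ...and not at untouched cells (same channel other band; other channel)
  expect_lt(rel_shift("Ch1", "beta", "EN"), 0.08)
  expect_lt(rel_shift("Ch2", "theta", "EN"), 0.08)
  ## estimated H moves by less than 0.05 at untouched cells
  h_shift <- function(ch, band) {
    v <- tb[tb$channel == ch & tb$band == band & tb$feature == "H", ]
    g <- grp[tb$channel == ch & tb$band == band & tb$feature == "H"]
    abs(diff(tapply(v$value, g, mean)))
  }
  expect_lt(h_shift("Ch1", "alpha"), 0.05)
  expect_lt(h_shift("Ch2", "theta"), 0.05)
})

test_that("null cohort keeps two-group t-statistics calibrated", {
  ## no injected effects: the fraction of |t| rejections at alpha = 0.05
  ## across all (channel, band, feature) cells stays inside the binomial
  ## 99.9% envelope around 0.05
  fx <- fixture("null_cft_small", function() {
    cfg <- cohortConfig(c(8, 8), nChannels = 2, duration = 60, seed = 77)
    coh <- genCohort(cfg)
    pw <- extractCohortFeatures(coh$recordings, bandpass = FALSE)
    list(cft = aggregateWindows(pw, coh$subjects), subjects = coh$subjects)
  })
  tb <- featureTable(fx$cft)
  grp <- fx$subjects$group[match(tb$subject, fx$subjects$subject)]
  key <- interaction(tb$channel, tb$band, tb$feature, drop = TRUE)
  pvals <- vapply(levels(key), function(k) {
    sel <- key == k
    v <- tb$value[sel]; g <- grp[sel]
    if (sd(v) == 0 || anyNA(v)) return(NA_real_)
    t.test(v[g == "YG"], v[g == "OB"], var.equal = TRUE)$p.value
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  nrej <- sum(pvals < 0.05)
  bounds <- qbinom(c(0.0005, 0.9995), length(pvals), 0.05)
  expect_gte(nrej, bounds[1])
  expect_lte(nrej, bounds[2])
})

test_that("cohorts round-trip through disk formats", {
  cfg <- cohortConfig(c(2, 1), nChannels = 2, duration = 5, seed = 9)
  coh <- genCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir, format = "matrix", config = cfg)
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  expect_true(file.exists(file.path(dir, "config.txt")))
  rec <- readRecording(file.path(dir, "YG01.txt"))
  expect_equal(eegData(rec), eegData(coh$recordings$YG01), tolerance = 1e-7)
  expect_equal(samplingRate(rec), 256)
})
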