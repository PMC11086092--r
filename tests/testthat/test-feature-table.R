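mk_window_table <- function(values, status = NULL) {
  nw <- length(values)
  df <- data.frame(subject = "S1", channel = "Ch1", band = "theta",
                   window = seq_len(nw), feature = "EN", value = values,
                   status = if (is.null(status)) "ok" else status,
                   tau = 1L, m = 2L)
  df
}

mk_subjects <- function(ids = "S1", group = "YG") {
  data.frame(subject = ids, group = group, psqi = 3L)
}

test_that("window aggregation: means, counts, and the missing-data rule", {
  cft <- aggregateWindows(mk_window_table(rep(7, 12)), mk_subjects())
  tb <- featureTable(cft)
  expect_equal(tb$value, 7)
  expect_identical(tb$nWindows, 12L)

  cft2 <- aggregateWindows(mk_window_table(c(2, 4)), mk_subjects())
  expect_equal(featureTable(cft2)$value, 3)

  st <- c("degenerate", rep("ok", 11))
  cft3 <- aggregateWindows(mk_window_table(c(100, rep(2, 11)), st),
                           mk_subjects())
  expect_equal(featureTable(cft3)$value, 2)
  expect_identical(featureTable(cft3)$nWindows, 11L)

  allbad <- aggregateWindows(mk_window_table(rep(NA_real_, 3), "degenerate"),
                             mk_subjects())
  expect_true(is.na(featureTable(allbad)$value))
  expect_identical(featureTable(allbad)$status, "missing")
  expect_error(aggregateWindows(mk_window_table(1)[0, ], mk_subjects()),
               "nrow")
})

test_that("aggregation is invariant to window order", {
  set.seed(40)
  v <- rnorm(12)
  a <- aggregateWindows(mk_window_table(v), mk_subjects())
  shuffled <- mk_window_table(v)[sample(12), ]
  b <- aggregateWindows(shuffled, mk_subjects())
  expect_equal(featureTable(a)$value, featureTable(b)$value)
})

test_that("pair z-scoring: pooled moments, hand oracle, degenerate cells", {
  cft <- random_feature_table()
  pair <- groupPair(cft, "GA", "GB")
  z <- zscorePair(cft, pair)
  tb <- featureTable(z)
  key <- interaction(tb$channel, tb$band, tb$feature)
  mus <- tapply(tb$value, key, mean)
  sds <- tapply(tb$value, key, sd)
  expect_lt(max(abs(mus)), 1e-10)
  expect_lt(max(abs(sds - 1)), 1e-10)

  ## hand-computed oracle on one cell
  raw <- featureTable(cft)
  cell <- raw$channel == "Ch1" & raw$band == "delta" & raw$feature == "EN"
  x <- raw$value[cell]
  zhand <- (x - mean(x)) / sd(x)
  expect_equal(tb$value[cell], zhand, tolerance = 1e-12)

  ## explicit four-subject column against the direct formula (n-1 in the
  ## denominator): values 1..4 -> (x - 2.5) / sqrt(5/3)
  small <- random_feature_table(nA = 2, nB = 2, channels = "Ch1", seed = 43)
  ts <- featureTable(small)
  cell4 <- ts$channel == "Ch1" & ts$band == "delta" & ts$feature == "EN"
  ts$value[cell4] <- 1:4
  small2 <- new("CohortFeatureTable", table = ts, subjects = subjectInfo(small))
  z4 <- zscorePair(small2, groupPair(small2, "GA", "GB"))
  expect_equal(sort(featureTable(z4)$value[cell4]),
               sort((1:4 - 2.5) / sqrt(5 / 3)), tolerance = 1e-12)

  ## constant cell -> zeros with a warning
  raw2 <- random_feature_table(seed = 41)
  t2 <- featureTable(raw2)
  flat <- t2$channel == "Ch2" & t2$band == "alpha" & t2$feature == "H"
  t2$value[flat] <- 5
  cft2 <- new("CohortFeatureTable", table = t2, subjects = subjectInfo(raw2))
  expect_warning(z2 <- zscorePair(cft2, groupPair(cft2, "GA", "GB")),
                 "zero-variance")
  expect_true(all(featureTable(z2)$value[flat] == 0))
})

test_that("z-scoring is idempotent and label-blind", {
  cft <- random_feature_table(seed = 42)
  pair <- groupPair(cft, "GA", "GB")
  z1 <- zscorePair(cft, pair)
  z2 <- zscorePair(z1, pair)
  expect_equal(featureTable(z1)$value, featureTable(z2)$value,
               tolerance = 1e-10)
  ## permuting group labels leaves pooled z-scores unchanged
  si <- subjectInfo(cft)
  si$group <- rev(si$group)
  cftp <- new("CohortFeatureTable", table = featureTable(cft), subjects = si)
  zp <- zscorePair(cftp, groupPair(cftp, "GA", "GB"))
  tb1 <- featureTable(z1); tbp <- featureTable(zp)
  ord <- order(tb1$subject, tb1$channel, tb1$band, tb1$feature)
  ordp <- order(tbp$subject, tbp$channel, tbp$band, tbp$feature)
  expect_equal(tb1$value[ord], tbp$value[ordp], tolerance = 1e-12)
})

test_that("group pairs require disjoint non-empty sides", {
  cft <- random_feature_table()
  expect_error(groupPair(cft, "GA", "GA"), "differ")
  expect_error(groupPair(cft, "GA", "GX"), "empty group side")
  p <- groupPair(cft, "GA", "GB")
  expect_identical(p$name, "GA_vs_GB")
  expect_length(intersect(p$subjectsA, p$subjectsB), 0)
})
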