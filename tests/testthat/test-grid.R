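test_that("run_pair produces the full channel x band x classifier grid", {
  cft <- random_feature_table(nA = 6, nB = 6)
  pair <- groupPair(cft, "GA", "GB")
  specs <- classifierSpecs(c("Fine KNN", "Linear SVM"))
  grid <- runPair(cft, pair, specs = specs)
  g <- accuracyTable(grid)
  expect_identical(nrow(g), 3L * 5L * 2L)
  expect_true(all(g$accuracy >= 0 & g$accuracy <= 1))
  expect_identical(grid@nSubjects, 12L)
  ## determinism: identical inputs, identical grid
  grid2 <- runPair(cft, pair, specs = specs)
  expect_identical(accuracyTable(grid2), g)
})

test_that("an injected shift is detected at its cell and nowhere strongly", {
  cft <- random_feature_table(nA = 10, nB = 10, seed = 60,
                              shiftCell = c("Ch2", "theta"), shiftBy = 3)
  pair <- groupPair(cft, "GA", "GB")
  grid <- runPair(cft, pair, specs = classifierSpecs("Linear SVM"))
  g <- accuracyTable(grid)
  hit <- g$accuracy[g$channel == "Ch2" & g$band == "theta"]
  expect_gte(hit, 0.9)
  others <- g$accuracy[!(g$channel == "Ch2" & g$band == "theta")]
  expect_true(all(others <= 0.8))
})

test_that("summaries: band means and maxima, best classifier, ties", {
  cft <- random_feature_table(nA = 6, nB = 6, seed = 61)
  pair <- groupPair(cft, "GA", "GB")
  grid <- runPair(cft, pair, specs = classifierSpecs(c("Fine KNN",
                                                       "Medium KNN")))
  s <- summarizeGrid(grid)
  g <- accuracyTable(grid)
  for (i in seq_len(nrow(s$bandSummary))) {
    sel <- g$classifier == s$bandSummary$classifier[i] &
      g$band == s$bandSummary$band[i]
    expect_equal(s$bandSummary$mean[i], mean(g$accuracy[sel]))
    expect_equal(s$bandSummary$max[i], max(g$accuracy[sel]))
    expect_lte(s$bandSummary$mean[i], s$bandSummary$max[i])
  }
  expect_identical(dim(s$bestBandTable), c(2L, 5L))

  ## all-equal grid: every classifier tied, first by name reported
  geq <- g; geq$accuracy <- 0.5
  grid_eq <- new("AccuracyGrid", grid = geq, pair = grid@pair,
                 nSubjects = grid@nSubjects, normalization = "pooled")
  expect_message(seq_ <- summarizeGrid(grid_eq), "tie")
  expect_identical(seq_$best, sort(unique(geq$classifier))[1])
  expect_error(summarizeGrid(new("AccuracyGrid",
                                 grid = geq[0, ], pair = c("a", "b"),
                                 nSubjects = 0L,
                                 normalization = "pooled")),
               "empty")
})

test_that("scalp map renders with coordinates and falls back without", {
  cft <- random_feature_table(nA = 6, nB = 6, seed = 62,
                              channels = paste0("Ch", 1:4))
  grid <- runPair(cft, groupPair(cft, "GA", "GB"),
                  specs = classifierSpecs("Fine KNN"))
  png1 <- withr::local_tempfile(fileext = ".png")
  z <- scalpMap(grid, coords = defaultScalpCoords(4), band = "alpha",
                file = png1)
  expect_true(file.exists(png1) && file.size(png1) > 0)
  expect_true(is.matrix(z))
  ## uniform accuracies -> uniform interpolated field
  gu <- accuracyTable(grid); gu$accuracy <- 0.7
  grid_u <- new("AccuracyGrid", grid = gu, pair = grid@pair,
                nSubjects = grid@nSubjects, normalization = "pooled")
  png2 <- withr::local_tempfile(fileext = ".png")
  zu <- scalpMap(grid_u, coords = defaultScalpCoords(4), band = "alpha",
                 classifier = "Fine KNN", file = png2)
  expect_lt(diff(range(zu, na.rm = TRUE)), 1e-9)
  ## unknown montage -> labeled bar chart fallback with a warning
  png3 <- withr::local_tempfile(fileext = ".png")
  expect_warning(zb <- scalpMap(grid, coords = data.frame(label = "X1",
                                                          x = 0, y = 0),
                                band = "alpha", file = png3),
                 "falling back")
  expect_named(zb)
})

test_that("fold-safe normalization is available and differs from pooled", {
  cft <- random_feature_table(nA = 7, nB = 7, seed = 63)
  pair <- groupPair(cft, "GA", "GB")
  gp <- runPair(cft, pair, specs = classifierSpecs("Fine KNN"),
                normalization = "pooled")
  gf <- runPair(cft, pair, specs = classifierSpecs("Fine KNN"),
                normalization = "foldwise")
  expect_identical(gp@normalization, "pooled")
  expect_identical(gf@normalization, "foldwise")
  expect_identical(dim(accuracyTable(gp)), dim(accuracyTable(gf)))
})
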