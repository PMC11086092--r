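# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; no data files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## A small two-group cohort with a strong theta hurst effect on channel 1,
## used by the generator-locality and feature-table tests.
effect_cohort_features <- function() {
  fixture("effect_cft", function() {
    eff <- data.frame(channel = 1, band = "theta", family = "hurst",
                      magnitude = 0.25)
    cfg <- cohortConfig(c(6, 6), nChannels = 2, duration = 60,
                        effects = eff, seed = 421)
    coh <- genCohort(cfg)
    pw <- extractCohortFeatures(coh$recordings, bandpass = FALSE)
    list(cft = aggregateWindows(pw, coh$subjects), subjects = coh$subjects,
         perWindow = pw)
  })
}

## A random CohortFeatureTable built directly (no signal processing), for
## classifier-grid bookkeeping tests.
random_feature_table <- function(nA = 8, nB = 8, channels = c("Ch1", "Ch2", "Ch3"),
                                 seed = 99, shiftCell = NULL, shiftBy = 0) {
  set.seed(seed)
  subjects <- data.frame(
    subject = c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB))),
    group = rep(c("GA", "GB"), c(nA, nB)),
    psqi = c(sample(0:5, nA, TRUE), sample(6:15, nB, TRUE)))
  grid <- expand.grid(subject = subjects$subject, channel = channels,
                      band = bandNames(), feature = featureNames(),
                      stringsAsFactors = FALSE)
  grid$value <- rnorm(nrow(grid))
  if (!is.null(shiftCell)) {
    sel <- grid$channel == shiftCell[1] & grid$band == shiftCell[2] &
      grid$subject %in% subjects$subject[subjects$group == "GB"]
    grid$value[sel] <- grid$value[sel] + shiftBy
  }
  grid$nWindows <- 12L
  grid$status <- "ok"
  new("CohortFeatureTable", table = grid, subjects = subjects)
}
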