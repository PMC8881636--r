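# Brute-force oracle for the adaptive window: enumerate every candidate
# start inside the search range and pick the best direction-signed mean.
bruteAdaptive <- function(series, time, fs, searchRange, span, direction) {
  L <- as.integer(round(span * fs / 1000)) + 1L
  best <- NULL; bestVal <- -Inf
  for (s in seq_along(time)) {
    e <- s + L - 1L
    if (e > length(time)) break
    if (time[s] < searchRange[1] - 1e-9 || time[e] > searchRange[2] + 1e-9)
      next
    v <- direction * mean(series[s:e])
    if (v > bestVal + 1e-12) { bestVal <- v; best <- c(time[s], time[e]) }
  }
  best
}

test_that("mean cluster amplitude averages the inclusive-endpoint window", {
  es <- makeEpochs(array(2, c(1, 4, 226)))
  w <- computeErp(es, "high")
  expect_equal(meanClusterAmplitude(w, 1:4, c(240, 300)), 2)
  # at 250 Hz the 240-300 ms window holds exactly 16 samples
  expect_length(windowSamples(timeAxis(es), c(240, 300)), 16L)
  # brute-force check on random data
  es2 <- randomEpochs(nTrials = 2L, nSensors = 5L, seed = 21L)
  w2 <- computeErp(es2, "high")
  idx <- which(timeAxis(es2) >= 240 & timeAxis(es2) <= 300)
  expect_equal(meanClusterAmplitude(w2, c(1L, 3L), c(240, 300)),
               mean(w2@data[c(1, 3), idx]), tolerance = 1e-12)
  # single sensor, single-sample window
  expect_equal(meanClusterAmplitude(w2, 2L, c(240, 240)), w2@data[2, idx[1]])
  expect_error(meanClusterAmplitude(w2, 1L, c(241, 243)), "no samples")
})

test_that("adaptive window matches the exhaustive slide oracle", {
  fs <- 250
  time <- seq(-100, 800, by = 4)
  spec <- defaultComponentSpecs(4L)$EPN
  spec@cluster <- 1:2

  mkDiff <- function(series)
    new("ERPWaveform", data = rbind(series, series), fs = fs, time = time,
        nTrials = 2L, condition = "difference")

  # negative Hanning bump centred at 280 ms
  bump <- mkDiff(-hannTemplate(time, 280, 80))
  expect_equal(adaptiveWindow(bump, spec),
               bruteAdaptive(bump@data[1, ], time, fs, c(150, 350), 60, -1))
  # random difference series agree with the oracle too
  for (seed in 1:5) {
    set.seed(seed)
    d <- mkDiff(rnorm(length(time)))
    expect_equal(adaptiveWindow(d, spec),
                 bruteAdaptive(d@data[1, ], time, fs, c(150, 350), 60, -1))
  }
  # flat difference: earliest admissible window (tie-break)
  flat <- mkDiff(numeric(length(time)))
  w <- adaptiveWindow(flat, spec)
  expect_equal(w[1], 152)           # first sample time >= 150 at 4 ms grid
  expect_equal(w[2], 152 + 60)
  # monotone-decreasing ramp: latest admissible window for a negative effect
  ramp <- mkDiff(-as.numeric(time))
  wr <- adaptiveWindow(ramp, spec)
  expect_equal(wr[2], 348)          # last sample time <= 350
  # span longer than the search range errors
  bad <- spec; bad@span <- 90; bad@searchRange <- c(150, 350)
  bad@searchRange <- c(300, 350)
  expect_error(adaptiveWindow(flat, bad), "search range")
})

test_that("zero-noise injected effect is recovered exactly by scoring", {
  par <- cleanParams(epnEffectAmp = -3, lppEffectAmp = 0,
                     effectSpan = c(EPN = 120, LPP = 160))
  es <- generateSubject(par, 1L)
  specs <- defaultComponentSpecs(8L)
  sc <- scoreComponent(es, specs$EPN, "adaptive")
  # adaptive window covers the injected latency (270 ms)
  expect_lte(sc$windowUsed[1], 270)
  expect_gte(sc$windowUsed[2], 270)
  # difference equals -3 x mean template weight over the selected window
  idx <- which(timeAxis(es) >= sc$windowUsed[1] - 1e-9 &
                 timeAxis(es) <= sc$windowUsed[2] + 1e-9)
  wbar <- mean(hannTemplate(timeAxis(es), 270, 120)[idx])
  expect_equal(sc$difference, -3 * wbar, tolerance = 1e-12)
  expect_equal(sc$difference, sc$meanHigh - sc$meanLow)
})

test_that("adaptive selection dominates the fixed window in the effect direction", {
  specs <- defaultComponentSpecs(8L)
  for (i in 1:30) {
    par <- tinyParams(nTrialsPerCondition = 8L, seed = 900L + i)
    es <- generateSubject(par, 1L)
    for (spec in specs) {
      a <- scoreComponent(es, spec, "adaptive")$difference
      f <- scoreComponent(es, spec, "fixed")$difference
      expect_gte(spec@direction * a, spec@direction * f - 1e-12)
    }
  }
})

test_that("scores are invariant to trial order permutations", {
  es <- randomEpochs(nTrials = 10L, nSensors = 4L, seed = 31L)
  set.seed(1); perm <- sample(10L)
  specs <- defaultComponentSpecs(4L)
  for (mode in c("fixed", "adaptive")) {
    a <- scoreComponent(es, specs$EPN, mode)
    b <- scoreComponent(es[perm], specs$EPN, mode)
    expect_equal(a$difference, b$difference, tolerance = 1e-12)
    expect_equal(a$windowUsed, b$windowUsed)
  }
})

test_that("shipped cluster files match the published definitions", {
  epn <- readClusterJson(system.file("extdata",
                                     "cluster_epn_hcgsn256.json",
                                     package = "erpcase"))
  lpp <- readClusterJson(system.file("extdata",
                                     "cluster_lpp_hcgsn256.json",
                                     package = "erpcase"))
  expect_length(epn$sensor_ids, 41L)
  expect_length(lpp$sensor_ids, 40L)
  cl <- defaultClusters(257L)
  expect_equal(epn$sensor_ids, cl$posterior)
  expect_equal(lpp$sensor_ids, cl$central)
})
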