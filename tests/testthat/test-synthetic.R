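test_that("all-zero model produces exactly zero amplitudes", {
  par <- cleanParams(epnEffectAmp = 0, lppEffectAmp = 0)
  es <- generateSubject(par, 1L)
  expect_true(all(epochData(es) == 0))
  expect_equal(nTrials(es), 40L)
})

test_that("generation is bit-identical under the same seed and arguments", {
  par <- tinyParams()
  a <- generateSubject(par, 2L)
  b <- generateSubject(par, 2L)
  expect_identical(epochData(a), epochData(b))
  expect_identical(conditionLabels(a), conditionLabels(b))
  # different subject index gives different data
  c <- generateSubject(par, 3L)
  expect_false(identical(epochData(a), epochData(c)))
})

test_that("injected effect matches the closed-form Hanning template sum", {
  par <- cleanParams(epnEffectAmp = -3, lppEffectAmp = 0,
                     effectLatency = c(EPN = 270, LPP = 430),
                     effectSpan = c(EPN = 60, LPP = 160))
  es <- generateSubject(par, 1L)
  time <- timeAxis(es)
  idx <- which(time >= 240 & time <= 300)
  # independent closed form: raised cosine on [240, 300], peak at 270
  w <- 0.5 * (1 - cos(2 * pi * (time[idx] - 240) / 60))
  cond <- conditionLabels(es)
  post <- defaultClusters(8L)$posterior
  diffs <- apply(epochData(es)[cond == "high", post, idx, drop = FALSE],
                 1L, mean) -
    mean(epochData(es)[cond == "low", post, idx])
  expect_equal(mean(diffs), -3 * mean(w), tolerance = 1e-12)
  # off-cluster sensors carry no effect
  offCluster <- setdiff(seq_len(8L), c(post, defaultClusters(8L)$central))
  expect_true(all(epochData(es)[, offCluster, ] == 0))
})

test_that("effect support outside the epoch or search range errors by name", {
  par <- tinyParams()
  par@effectLatency[["EPN"]] <- 340
  expect_error(generateSubject(par, 1L), "EPN")
  par <- tinyParams()
  par@effectLatency[["LPP"]] <- 720
  expect_error(generateSubject(par, 1L), "LPP")
})

test_that("mirror labels are balanced within each condition", {
  es <- generateSubject(tinyParams(nTrialsPerCondition = 30L), 1L)
  for (cond in c("high", "low")) {
    m <- mirrorLabels(es)[conditionLabels(es) == cond]
    expect_equal(sum(m == "left"), 15L)
    expect_equal(sum(m == "right"), 15L)
  }
})

test_that("a study yields one EpochSet per subject x system with distinct keys", {
  par <- tinyParams(nTrialsPerCondition = 4L,
                    systems = c("sexual_reproduction", "disease_avoidance",
                                "predator_fear"),
                    noiseSd = 1)
  par@nSubjects <- 2L
  study <- generateStudy(par)
  expect_length(study, 6L)
  expect_equal(anyDuplicated(names(study)), 0L)
  keys <- vapply(study, function(e)
    paste(subjectId(e), behaviorSystem(e)), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("zero between-subject variance gives identical injected differences", {
  par <- cleanParams(epnEffectAmp = -2)
  par@nSubjects <- 2L
  study <- generateStudy(par)
  d <- lapply(study, function(es) {
    cond <- conditionLabels(es)
    apply(epochData(es)[cond == "high", , , drop = FALSE], c(2, 3), mean) -
      apply(epochData(es)[cond == "low", , , drop = FALSE], c(2, 3), mean)
  })
  expect_equal(d[[1]], d[[2]], tolerance = 1e-12)
})

test_that("null generator: window-mean condition difference centred on zero", {
  # 200 effect-free subjects; the mean fixed-window difference across
  # subjects must sit within 4 standard errors of zero
  specs <- defaultComponentSpecs(8L)
  diffs <- vapply(1:200, function(i) {
    par <- cleanParams(epnEffectAmp = 0, lppEffectAmp = 0, noiseSd = 10,
                       nTrialsPerCondition = 10L, seed = 500L + i)
    es <- generateSubject(par, 1L)
    scoreComponent(es, specs$EPN, "fixed")$difference
  }, numeric(1L))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se)
})

test_that("empirical per-sensor noise SD matches noiseSd within 5%", {
  par <- cleanParams(epnEffectAmp = 0, lppEffectAmp = 0, noiseSd = 20,
                     nTrialsPerCondition = 100L)
  es <- generateSubject(par, 1L)
  sds <- apply(epochData(es), 2L, sd)
  expect_true(all(abs(sds - 20) / 20 < 0.05))
})

test_that("generated noise has the requested 1/f spectral slope", {
  for (beta in c(0.5, 1)) {
    par <- cleanParams(epnEffectAmp = 0, lppEffectAmp = 0, noiseSd = 5,
                       nTrialsPerCondition = 150L, spatialCorr = 0,
                       noiseExponent = beta, seed = 77L)
    es <- generateSubject(par, 1L)
    x <- epochData(es)[, 1L, ]
    ps <- apply(x, 1L, function(v) Mod(fft(v))^2)   # samples x trials
    f <- (seq_len(nrow(ps)) - 1L) * samplingRate(es) / nrow(ps)
    sel <- f >= 1 & f <= 40
    slope <- coef(lm(log10(rowMeans(ps)[sel]) ~ log10(f[sel])))[2L]
    expect_lt(abs(slope + beta), 0.2)
  }
})
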