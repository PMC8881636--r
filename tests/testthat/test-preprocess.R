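test_that("designed magnitude response hits -3 dB at both half-power cutoffs", {
  spec <- filterSpec()
  fs <- 250
  gLp <- filterMagnitude(spec, 40, fs, "lowpass")
  gHp <- filterMagnitude(spec, 0.06, fs, "highpass")
  expect_lt(abs(gLp - sqrt(0.5)) / sqrt(0.5), 0.01)
  expect_lt(abs(gHp - sqrt(0.5)) / sqrt(0.5), 0.01)
  # passband: 10 Hz gain within 1% of 1 for one low-pass pass
  expect_lt(abs(filterMagnitude(spec, 10, fs, "lowpass") - 1), 0.01)
  # stopband of the order-19 low-pass is steep: below -40 dB at 50 Hz
  expect_lt(20 * log10(filterMagnitude(spec, 50, fs, "lowpass")), -40)
})

test_that("filtering preserves shape, zeros, and steady-state sinusoids", {
  z <- makeEpochs(array(0, c(2, 3, 250)))
  zf <- applyFilters(z)
  expect_equal(dim(epochData(zf)), c(2L, 3L, 250L))
  expect_true(all(epochData(zf) == 0))

  # causal single cascade: 10 Hz sinusoid passes at unit amplitude
  fs <- 250
  t <- seq(0, 6, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  es <- makeEpochs(array(rep(x, each = 1), c(1, 1, length(t))), fs = fs)
  yf <- applyFilters(es, filterSpec(phaseMode = "causal"))
  ss <- epochData(yf)[1, 1, (length(t) - 400):length(t)]
  expect_lt(abs((max(ss) - min(ss)) / 2 - 1), 0.01)
})

test_that("cutoff at or above Nyquist and too-short epochs error", {
  es <- makeEpochs(array(0, c(1, 1, 250)))
  expect_error(applyFilters(es, filterSpec(lowpassCutoff = 125)), "Nyquist")
  short <- makeEpochs(array(0, c(1, 1, 20)))
  expect_error(applyFilters(short), "at least")
})

test_that("baseline and average-reference identities hold simultaneously", {
  es <- randomEpochs(nTrials = 6L, nSensors = 5L, seed = 3L)
  out <- baselineAndReference(es)
  d <- epochData(out)
  # across-sensor sum is zero at every trial/sample
  expect_lt(max(abs(apply(d, c(1, 3), sum))), 1e-10)
  # per trial/sensor baseline mean is zero
  idx <- which(timeAxis(out) >= -100 & timeAxis(out) < 0)
  expect_lt(max(abs(apply(d[, , idx, drop = FALSE], c(1, 2), mean))), 1e-10)
  # idempotence: applying the operation twice changes nothing
  expect_equal(epochData(baselineAndReference(out)), d, tolerance = 1e-12)
})

test_that("constant per-sensor offsets are removed by baseline adjustment", {
  es <- randomEpochs(nTrials = 4L, nSensors = 3L, seed = 9L)
  offs <- c(5, -2, 40)
  shifted <- es
  for (s in 1:3) shifted@data[, s, ] <- shifted@data[, s, ] + offs[s]
  expect_equal(epochData(baselineAndReference(shifted)),
               epochData(baselineAndReference(es)), tolerance = 1e-10)
})

test_that("empty baseline interval errors", {
  es <- makeEpochs(array(0, c(1, 1, 50)), fs = 250)
  # at 250 Hz samples fall at -100, -96, ...; [-99, -97) contains none
  expect_error(baselineAndReference(es, baseline = c(-99, -97)),
               "no samples")
})

test_that("artifact rejection drops exactly the spiked trials", {
  es <- randomEpochs(nTrials = 12L, nSensors = 4L, seed = 5L)
  r <- rejectArtifacts(es, absThreshold = Inf)
  expect_equal(nTrials(r$epochs), 12L)
  expect_equal(nrow(r$log), 0L)

  spiked <- es
  k <- c(2L, 7L, 11L)
  for (tr in k) spiked@data[tr, 2L, 30L] <- 1000
  r2 <- rejectArtifacts(spiked, absThreshold = 100)
  expect_equal(nTrials(r2$epochs), 9L)
  expect_equal(r2$log$trial_index, k)
  expect_equal(r2$log$sensor, rep(2L, 3L))
  expect_equal(r2$log$value, rep(1000, 3L))
  expect_error(rejectArtifacts(spiked, absThreshold = 1e-9), "all trials")
})

test_that("trial equating keeps a seeded subset of the larger condition", {
  # counts mirror the study's reported per-system means (447 vs 430)
  nH <- 447L; nL <- 430L
  es <- makeEpochs(array(seq_len((nH + nL) * 1 * 5), c(nH + nL, 1, 5)),
                   condition = c(rep("high", nH), rep("low", nL)))
  eq <- equateTrials(es, seed = 4L)
  expect_equal(as.integer(table(conditionLabels(eq))["high"]), 430L)
  expect_equal(as.integer(table(conditionLabels(eq))["low"]), 430L)
  # kept trials are a subset of the originals, order preserved
  expect_true(all(epochData(eq)[, 1, 1] %in% epochData(es)[, 1, 1]))
  expect_true(!is.unsorted(match(epochData(eq)[, 1, 1],
                                 epochData(es)[, 1, 1])))
  # smaller condition untouched
  expect_equal(sum(conditionLabels(eq) == "low" &
                     epochData(eq)[, 1, 1] > nH), 430L)
  # determinism and no-op when balanced
  eq2 <- equateTrials(es, seed = 4L)
  expect_identical(epochData(eq), epochData(eq2))
  bal <- makeEpochs(array(rnorm(40), c(8, 1, 5)))
  expect_identical(epochData(equateTrials(bal, 1L)), epochData(bal))
})

test_that("ERP averaging equals a brute-force loop", {
  es <- randomEpochs(nTrials = 5L, nSensors = 3L, nSamples = 20L, seed = 8L)
  es@trialData$condition <- rep("high", 5L)
  w <- computeErp(es, "high")
  acc <- matrix(0, 3L, 20L)
  for (tr in 1:5) acc <- acc + epochData(es)[tr, , ]
  expect_equal(w@data, acc / 5, tolerance = 1e-12)
  expect_equal(w@nTrials, 5L)
  # single trial: waveform equals that trial
  one <- es[1]
  expect_equal(computeErp(one, "high")@data, epochData(es)[1, , ])
  expect_error(computeErp(es, "absent"), "no trials")
})

test_that("filtering commutes with splitting by condition", {
  es <- randomEpochs(nTrials = 8L, nSensors = 2L, seed = 12L)
  f <- filterSpec()
  whole <- applyFilters(es, f)
  avgWhole <- computeErp(whole, "high")@data
  split <- applyFilters(es[which(conditionLabels(es) == "high")], f)
  avgSplit <- computeErp(split, "high")@data
  expect_equal(avgWhole, avgSplit, tolerance = 1e-10)
})
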