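test_that("per-trial scores match a brute-force loop and average to the ERP score", {
  es <- randomEpochs(nTrials = 4L, nSensors = 4L, seed = 41L)
  cluster <- c(1L, 3L)
  window <- c(240, 300)
  scores <- perTrialScores(es, cluster, window)
  idx <- which(timeAxis(es) >= 240 & timeAxis(es) <= 300)
  for (tr in 1:4)
    expect_equal(scores[tr], mean(epochData(es)[tr, cluster, idx]),
                 tolerance = 1e-12)
  # condition means of per-trial scores equal the waveform-level means
  spec <- componentSpec("EPN", cluster, c(240, 300), c(150, 350), 60, -1)
  sc <- scoreComponent(es, spec, "fixed")
  cond <- conditionLabels(es)
  expect_equal(mean(scores[cond == "high"]), sc$meanHigh, tolerance = 1e-12)
  expect_equal(mean(scores[cond == "low"]), sc$meanLow, tolerance = 1e-12)
  # constant input gives that constant
  one <- makeEpochs(array(5, c(1, 2, 226)))
  expect_equal(perTrialScores(one, 1:2, c(0, 100)), 5)
})

test_that("bootstrap distribution: degenerate and symmetric cases", {
  # identical pooled values: every replicate difference is exactly 0
  d0 <- bootstrapDistribution(rep(3, 4), rep(3, 5), nBoot = 200L, seed = 1L)
  expect_true(all(d0 == 0))
  # identical score multisets: replicate mean within 3 Monte-Carlo SEs of 0
  s <- c(1, 2, 3)
  d <- bootstrapDistribution(s, s, nBoot = 50000L, seed = 2L)
  pooledVar <- mean((c(s, s) - mean(c(s, s)))^2)
  mcSe <- sqrt(pooledVar * (1 / 3 + 1 / 3) / 50000)
  expect_lt(abs(mean(d)), 3 * mcSe)
  # determinism under the seed
  expect_identical(d, bootstrapDistribution(s, s, nBoot = 50000L, seed = 2L))
})

test_that("bootstrap agrees with exhaustive 3+3 enumeration", {
  scores <- c(2.1, 3.4, 4.0, 1.0, 1.9, 2.5)
  exact <- exactBootstrap33(scores)
  boot <- bootstrapDistribution(scores[1:3], scores[4:6],
                                nBoot = 50000L, seed = 5L)
  # sup-norm distance between the two CDFs over the exact support
  grid <- sort(unique(exact))
  cdfE <- ecdf(exact)(grid)
  cdfB <- ecdf(boot)(grid)
  expect_lt(max(abs(cdfE - cdfB)), 0.01)
})

test_that("bootstrap p counts equal-or-more-extreme replicates", {
  # equality counts as extreme
  r <- bootstrapP(0, rep(0, 100), direction = -1, sidedness = "one")
  expect_equal(r$p, 1)
  expect_equal(r$extremeCount, 100L)
  # constructed distribution: 49 of 50000 at least as extreme
  dist <- c(rep(2, 49), rep(0, 50000 - 49))
  r2 <- bootstrapP(2, dist, direction = +1, sidedness = "one")
  expect_equal(r2$extremeCount, 49L)
  expect_equal(r2$p, 0.00098)
  flags <- classifySignificance(r2$p)
  expect_equal(unname(flags), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # more extreme than every replicate: p = 0, significant everywhere
  r3 <- bootstrapP(5, dist, direction = +1, sidedness = "one")
  expect_equal(r3$p, 0)
  expect_true(all(classifySignificance(r3$p)))
  # two-sided counts |d| >= |observed|
  r4 <- bootstrapP(-2, c(-3, -2, -1, 1, 2, 3, 0, 0, 0, 0), direction = -1,
                   sidedness = "two")
  expect_equal(r4$extremeCount, 4L)
})

test_that("significance grading uses strict inequalities", {
  expect_equal(unname(classifySignificance(0.0009)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(classifySignificance(0)))
  expect_false(any(classifySignificance(0.05)))
  expect_equal(unname(classifySignificance(0.02)),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("criterion count bounds reproduce the graded criteria at B = 50000", {
  expect_equal(criterionCountBound(50000, 0.05), 2500L)
  expect_equal(criterionCountBound(50000, 0.025), 1250L)
  expect_equal(criterionCountBound(50000, 0.01), 500L)
  expect_equal(criterionCountBound(50000, 0.001), 50L)
  expect_equal(criterionCountBound(50000, 0.00002), 1L)
})

test_that("p-values are invariant to trial relabeling and respond to shifts", {
  es <- randomEpochs(nTrials = 12L, nSensors = 4L, seed = 51L)
  specs <- defaultComponentSpecs(4L)["EPN"]
  cfg <- bootstrapConfig(nBoot = 2000L, seed = 9L)
  a <- runCaseAnalysis(es, specs, cfg, "fixed")
  set.seed(2); perm <- sample(12L)
  b <- runCaseAnalysis(es[perm], specs, cfg, "fixed")
  expect_equal(a$p_one_sided, b$p_one_sided)
  expect_equal(a$observed_difference, b$observed_difference,
               tolerance = 1e-12)

  # monotonicity: pushing the high scores toward the predicted (negative)
  # direction must not increase the one-sided p
  shifted <- es
  hi <- which(conditionLabels(es) == "high")
  shifted@data[hi, , ] <- shifted@data[hi, , ] - 5
  s <- runCaseAnalysis(shifted, specs, cfg, "fixed")
  expect_lte(s$p_one_sided, a$p_one_sided)
})

test_that("zero-noise subjects with large effects give p = 0 for both components", {
  par <- cleanParams(epnEffectAmp = -4, lppEffectAmp = 3, noiseSd = 0.01)
  es <- generateSubject(par, 1L)
  res <- runCaseAnalysis(es, defaultComponentSpecs(8L),
                         bootstrapConfig(nBoot = 1000L, seed = 3L),
                         "adaptive")
  expect_equal(res$p_one_sided, c(0, 0))
  expect_true(all(as.matrix(res[, grep("^sig_", names(res))])))
  # one- and two-sided tests agree when the effect matches the predicted
  # direction
  expect_equal(res$p_two_sided, c(0, 0))
})

test_that("window policies differ only in how replicates pick windows", {
  es <- randomEpochs(nTrials = 10L, nSensors = 4L, seed = 61L)
  specs <- defaultComponentSpecs(4L)["EPN"]
  fixedPol <- bootstrapConfig(nBoot = 300L, seed = 4L,
                              windowPolicy = "fixed_observed")
  resel <- bootstrapConfig(nBoot = 300L, seed = 4L,
                           windowPolicy = "reselect_per_replicate")
  a <- runCaseAnalysis(es, specs, fixedPol, "adaptive")
  b <- runCaseAnalysis(es, specs, resel, "adaptive")
  # same observed statistic and window either way
  expect_equal(a$observed_difference, b$observed_difference,
               tolerance = 1e-12)
  expect_equal(a$window_start, b$window_start)
  # reselection maximises inside each replicate, so its null distribution
  # is shifted toward the predicted direction relative to the fixed window:
  # the reselect p cannot be smaller
  expect_gte(b$p_one_sided, a$p_one_sided)
})

test_that("half splits preserve and partition the trials", {
  # balanced case: 12+12 -> 6+6 per half
  es <- makeEpochs(array(rnorm(24 * 2 * 10), c(24, 2, 10)))
  h <- splitHalves(es)
  expect_equal(as.integer(table(conditionLabels(h$first))), c(6L, 6L))
  expect_equal(as.integer(table(conditionLabels(h$second))), c(6L, 6L))
  # odd counts: 5+4 -> first 3+2, second 2+2
  es2 <- makeEpochs(array(rnorm(9 * 1 * 5), c(9, 1, 5)),
                    condition = c(rep("high", 5), rep("low", 4)))
  h2 <- splitHalves(es2)
  expect_equal(as.integer(table(conditionLabels(h2$first))[c("high", "low")]),
               c(3L, 2L))
  expect_equal(as.integer(table(conditionLabels(h2$second))[c("high", "low")]),
               c(2L, 2L))
  # union of halves is the original multiset, disjoint by construction
  all1 <- epochData(h2$first)[, 1, 1]
  all2 <- epochData(h2$second)[, 1, 1]
  expect_equal(sort(c(all1, all2)), sort(epochData(es2)[, 1, 1]))
  expect_error(splitHalves(makeEpochs(array(0, c(2, 1, 5)),
                                      condition = c("high", "low"))),
               "at least 2")
})
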