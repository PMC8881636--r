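# Shared fixtures: small parameter sets and hand-built epoch sets.

# Tiny montage / design for fast tests.
tinyParams <- function(..., nSensors = 8L, nTrialsPerCondition = 20L,
                       systems = "sexual_reproduction", seed = 11L) {
  syntheticParams(nSubjects = 4L, nSensors = nSensors,
                  nTrialsPerCondition = nTrialsPerCondition,
                  systems = systems, seed = seed, ...)
}

# Deterministic-signal params: no noise, no jitter, no trial scatter.
# Any of the defaults below may be overridden by name.
cleanParams <- function(...) {
  args <- list(noiseSd = 0, latencyJitterSd = 0, trialAmpSd = 0,
               subjectScaleSdlog = 0, baseErpAmp = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(tinyParams, args)
}

# EpochSet built directly from an array with alternating condition labels.
makeEpochs <- function(data, fs = 250, time = NULL,
                       condition = rep_len(c("high", "low"),
                                           dim(data)[1L]),
                       mirror = rep_len(c("left", "right"),
                                        dim(data)[1L])) {
  if (is.null(time))
    time <- seq(-100, by = 1000 / fs, length.out = dim(data)[3L])
  epochSet(data, fs = fs, time = time, condition = condition,
           mirror = mirror)
}

# Random small epoch set under a fixed seed.
randomEpochs <- function(nTrials = 10L, nSensors = 4L, nSamples = 226L,
                         seed = 1L, fs = 250) {
  set.seed(seed)
  makeEpochs(array(rnorm(nTrials * nSensors * nSamples),
                   dim = c(nTrials, nSensors, nSamples)), fs = fs)
}

# Exact bootstrap-difference distribution for 3+3 scores by full
# enumeration of all with-replacement assignments (216 x 216 outcomes).
exactBootstrap33 <- function(scores) {
  stopifnot(length(scores) == 6L)
  idx <- expand.grid(1:6, 1:6, 1:6)
  means <- rowMeans(matrix(scores[as.matrix(idx)], ncol = 3L))
  as.vector(outer(means, means, "-"))   # mean(high) - mean(low)
}
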