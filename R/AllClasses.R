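#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' EpochSet: epoched EEG for one subject and behavior system
#'
#' The unit of all analysis: a trials x sensors x samples amplitude tensor
#' (microvolts) with a uniform time axis in milliseconds, per-trial
#' condition (\code{"high"}/\code{"low"} arousal) and mirror
#' (\code{"left"}/\code{"right"}) labels.
#'
#' @slot data numeric array, trials x sensors x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot time numeric vector of sample times in ms; strictly increasing with
#'   step \code{1000/fs} and containing 0 (stimulus onset).
#' @slot trialData \code{DataFrame} with columns \code{condition} and
#'   \code{mirror}, one row per trial.
#' @slot subjectId character scalar.
#' @slot system behavior-system label (e.g. \code{"sexual_reproduction"}).
#' @slot provenance free-text description of where the data came from.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    fs = "numeric",
    time = "numeric",
    trialData = "DataFrame",
    subjectId = "character",
    system = "character",
    provenance = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x sensors x samples 3-D array")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(d) == 3L && nrow(object@trialData) != d[1L])
    msg <- c(msg, "trialData must have one row per trial")
  if (length(d) == 3L && length(object@time) != d[3L])
    msg <- c(msg, "time axis length must equal the number of samples")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all amplitudes must be finite")
  if (length(object@time) > 1L) {
    step <- diff(object@time)
    if (any(step <= 0) || any(abs(step - 1000 / object@fs) > 1e-6))
      msg <- c(msg, "time axis must be strictly increasing with step 1000/fs")
  }
  if (!all(c("condition", "mirror") %in% colnames(object@trialData)))
    msg <- c(msg, "trialData needs columns 'condition' and 'mirror'")
  if (length(msg)) msg else TRUE
})

#' FilterSpec: band-limiting filter parameters
#'
#' Cascaded Butterworth high-pass and low-pass filters. Cutoffs are
#' half-power (-3 dB) frequencies.
#'
#' @slot lowpassCutoff,lowpassOrder low-pass half-power cutoff (Hz) / order.
#' @slot highpassCutoff,highpassOrder high-pass half-power cutoff (Hz) / order.
#' @slot family filter family label; only \code{"butterworth"} is implemented.
#' @slot phaseMode \code{"zero_phase"} (forward-backward) or \code{"causal"}.
#'
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(
    lowpassCutoff = "numeric", lowpassOrder = "integer",
    highpassCutoff = "numeric", highpassOrder = "integer",
    family = "character", phaseMode = "character"
  )
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (!(object@highpassCutoff > 0))
    msg <- c(msg, "highpassCutoff must be > 0")
  if (!(object@lowpassCutoff > object@highpassCutoff))
    msg <- c(msg, "lowpassCutoff must exceed highpassCutoff")
  if (object@lowpassOrder < 1L || object@highpassOrder < 1L)
    msg <- c(msg, "filter orders must be >= 1")
  if (!object@phaseMode %in% c("zero_phase", "causal"))
    msg <- c(msg, "phaseMode must be 'zero_phase' or 'causal'")
  if (length(msg)) msg else TRUE
})

#' ERPWaveform: a trial-averaged waveform
#'
#' @slot data sensors x samples matrix of mean amplitudes (microvolts).
#' @slot fs sampling rate (Hz).
#' @slot time sample times (ms).
#' @slot nTrials number of trials averaged.
#' @slot condition condition label, or \code{"difference"}.
#'
#' @exportClass ERPWaveform
setClass("ERPWaveform",
  representation(
    data = "matrix", fs = "numeric", time = "numeric",
    nTrials = "integer", condition = "character"
  )
)

setValidity("ERPWaveform", function(object) {
  msg <- character()
  if (ncol(object@data) != length(object@time))
    msg <- c(msg, "sample count must match time axis")
  if (object@nTrials < 1L)
    msg <- c(msg, "nTrials must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ComponentSpec: how an ERP component is scored
#'
#' Defines a component (EPN or LPP) by its sensor cluster, fixed scoring
#' window, adaptive search range, adaptive window span, and expected
#' direction of the emotional-modulation effect (high minus low arousal).
#'
#' @slot name component label, conventionally \code{"EPN"} or \code{"LPP"}.
#' @slot clusterName label of the sensor cluster.
#' @slot cluster sorted unique 1-based sensor indices.
#' @slot fixedWindow length-2 ms interval used in fixed-window scoring.
#' @slot searchRange length-2 ms interval the adaptive window may occupy.
#' @slot span adaptive window length in ms.
#' @slot direction expected sign of the effect: -1 (EPN) or +1 (LPP).
#'
#' @exportClass ComponentSpec
setClass("ComponentSpec",
  representation(
    name = "character", clusterName = "character", cluster = "integer",
    fixedWindow = "numeric", searchRange = "numeric",
    span = "numeric", direction = "numeric"
  )
)

setValidity("ComponentSpec", function(object) {
  msg <- character()
  if (length(object@cluster) == 0L || any(object@cluster < 1L))
    msg <- c(msg, "cluster must be non-empty 1-based sensor indices")
  if (is.unsorted(object@cluster, strictly = TRUE))
    msg <- c(msg, "cluster indices must be sorted and unique")
  if (length(object@fixedWindow) != 2L || diff(object@fixedWindow) <= 0)
    msg <- c(msg, "fixedWindow must be an increasing ms interval")
  if (length(object@searchRange) != 2L || diff(object@searchRange) <= 0)
    msg <- c(msg, "searchRange must be an increasing ms interval")
  if (object@span <= 0 || object@span > diff(object@searchRange))
    msg <- c(msg, "span must be positive and no longer than searchRange")
  if (!object@direction %in% c(-1, 1))
    msg <- c(msg, "direction must be -1 or +1")
  if (length(msg)) msg else TRUE
})

#' BootstrapConfig: single-subject bootstrap test settings
#'
#' @slot nBoot number of bootstrap repetitions (study value: 50000).
#' @slot seed integer seed.
#' @slot sidedness \code{"one"} or \code{"two"} (flags use the one-sided p).
#' @slot criteria strictly decreasing p-value criteria.
#' @slot windowPolicy \code{"fixed_observed"} (adaptive window chosen once
#'   from the observed data and reused in every replicate) or
#'   \code{"reselect_per_replicate"}.
#'
#' @exportClass BootstrapConfig
setClass("BootstrapConfig",
  representation(
    nBoot = "integer", seed = "integer", sidedness = "character",
    criteria = "numeric", windowPolicy = "character"
  )
)

setValidity("BootstrapConfig", function(object) {
  msg <- character()
  if (object@nBoot < 1L) msg <- c(msg, "nBoot must be >= 1")
  if (any(object@criteria <= 0) || any(object@criteria >= 1) ||
      is.unsorted(rev(object@criteria), strictly = TRUE))
    msg <- c(msg, "criteria must be strictly decreasing within (0, 1)")
  if (!object@sidedness %in% c("one", "two"))
    msg <- c(msg, "sidedness must be 'one' or 'two'")
  if (!object@windowPolicy %in% c("fixed_observed", "reselect_per_replicate"))
    msg <- c(msg, "unknown windowPolicy")
  if (length(msg)) msg else TRUE
})

#' SnrConfig: bootstrap signal-to-noise-ratio settings
#'
#' @slot nBoot bootstrap repetitions.
#' @slot ciLevel central confidence level (default 0.90).
#' @slot preWindow ms interval of pre-stimulus (noise) samples, half-open
#'   \code{[pre1, pre2)}.
#' @slot postWindow ms interval of post-stimulus (signal) samples, half-open
#'   \code{(post1, post2]}; \code{NA} means "to the end of the epoch".
#' @slot dbThreshold minimum acceptable lower CI bound in dB (default 3).
#' @slot seed integer seed.
#'
#' @exportClass SnrConfig
setClass("SnrConfig",
  representation(
    nBoot = "integer", ciLevel = "numeric",
    preWindow = "numeric", postWindow = "numeric",
    dbThreshold = "numeric", seed = "integer"
  )
)

setValidity("SnrConfig", function(object) {
  msg <- character()
  if (object@ciLevel <= 0 || object@ciLevel >= 1)
    msg <- c(msg, "ciLevel must be in (0, 1)")
  if (object@nBoot < 1L) msg <- c(msg, "nBoot must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticParams: controls for the synthetic epoched-EEG generator
#'
#' Defaults emulate the study design: 600 trials per picture category,
#' 250 Hz sampling, epochs from -100 to 800 ms, three behavior systems, an
#' EPN-like posterior negativity and an LPP-like centro-parietal positivity
#' for high-arousal trials, embedded in spatially correlated 1/f noise.
#'
#' @slot nSubjects,nSensors,nTrialsPerCondition design sizes.
#' @slot fs sampling rate (Hz).
#' @slot epochStart,epochEnd epoch limits (ms), start < 0 < end.
#' @slot systems behavior-system labels.
#' @slot noiseSd per-sensor noise standard deviation (microvolts).
#' @slot noiseExponent spectral slope beta of the 1/f^beta noise.
#' @slot spatialCorr fraction (0-1) of noise variance shared across sensors.
#' @slot baseErpAmp condition-independent evoked amplitude (microvolts);
#'   positive on the posterior cluster, negative on the central cluster.
#' @slot epnEffectAmp,lppEffectAmp named per-system peak effect amplitudes
#'   (microvolts; EPN negative, LPP positive) added on high-arousal trials.
#' @slot mirrorEffectAmp peak amplitude added on left-mirror trials
#'   (default 0: mirrors are a built-in null).
#' @slot effectLatency named ms centers of the EPN/LPP effect bumps.
#' @slot effectSpan named ms full widths of the Hanning effect bumps.
#' @slot latencyJitterSd across-trial latency jitter SD (ms).
#' @slot trialAmpSd across-trial additive amplitude SD (microvolts).
#' @slot subjectScaleSdlog log-SD of the per-subject lognormal effect scale.
#' @slot posteriorCluster,centralCluster sensor indices the effects load on.
#' @slot seed root integer seed.
#'
#' @exportClass SyntheticParams
setClass("SyntheticParams",
  representation(
    nSubjects = "integer", nSensors = "integer", fs = "numeric",
    epochStart = "numeric", epochEnd = "numeric",
    nTrialsPerCondition = "integer", systems = "character",
    noiseSd = "numeric", noiseExponent = "numeric", spatialCorr = "numeric",
    baseErpAmp = "numeric", epnEffectAmp = "numeric", lppEffectAmp = "numeric",
    mirrorEffectAmp = "numeric",
    effectLatency = "numeric", effectSpan = "numeric",
    latencyJitterSd = "numeric", trialAmpSd = "numeric",
    subjectScaleSdlog = "numeric",
    posteriorCluster = "integer", centralCluster = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticParams", function(object) {
  msg <- character()
  if (!(object@epochStart < 0 && 0 < object@epochEnd))
    msg <- c(msg, "epoch must satisfy epochStart < 0 < epochEnd")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@nSubjects < 1L || object@nSensors < 1L ||
      object@nTrialsPerCondition < 1L)
    msg <- c(msg, "all counts must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@latencyJitterSd < 0) msg <- c(msg, "latencyJitterSd must be >= 0")
  if (object@spatialCorr < 0 || object@spatialCorr > 1)
    msg <- c(msg, "spatialCorr must be in [0, 1]")
  for (comp in c("EPN", "LPP")) {
    lo <- object@effectLatency[[comp]] - object@effectSpan[[comp]] / 2
    hi <- object@effectLatency[[comp]] + object@effectSpan[[comp]] / 2
    if (lo < object@epochStart || hi > object@epochEnd)
      msg <- c(msg, sprintf("%s effect support [%g, %g] ms lies outside the epoch",
                            comp, lo, hi))
  }
  if (max(object@posteriorCluster, object@centralCluster) > object@nSensors)
    msg <- c(msg, "cluster sensor indices exceed nSensors")
  if (length(msg)) msg else TRUE
})
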