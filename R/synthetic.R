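# Synthetic epoched-EEG generator.
#
# Additive per-trial model: spatially correlated 1/f noise + a
# condition-independent evoked shape on both clusters + condition-dependent
# Hanning-bump effect templates (EPN-like negativity on the posterior
# cluster, LPP-like positivity on the central cluster) on high-arousal
# trials. Mirror labels carry no signal unless mirrorEffectAmp is set.

#' Default sensor clusters for a given montage size
#'
#' For 257-channel data (HydroCel 256 net plus vertex channel) returns the
#' published occipito-parietal EPN cluster (41 sensors) and centro-parietal
#' LPP cluster (40 sensors, including the vertex channel 257). For 256
#' channels the vertex id is dropped from the LPP cluster. For smaller
#' montages a generic front/back split of the requested size is returned.
#'
#' @param nSensors number of sensors in the montage.
#' @return list with integer vectors \code{posterior} and \code{central}.
#' @export
defaultClusters <- function(nSensors) {
  epn256 <- c(106:108, 113:117, 121:126, 133:139, 145:151, 156:160,
              165:169, 174:176)
  lpp256 <- c(6:9, 15:17, 23, 24, 30, 42:45, 51:53, 59, 60, 79:81, 89,
              130:132, 143, 144, 155, 183:186, 196:198, 206, 207, 215, 257)
  if (nSensors >= 257L)
    return(list(posterior = epn256, central = lpp256))
  if (nSensors == 256L)
    return(list(posterior = epn256, central = lpp256[lpp256 <= 256L]))
  k <- max(1L, floor(nSensors / 3))
  list(posterior = seq_len(k),
       central = seq.int(nSensors - k + 1L, nSensors))
}

#' Construct generator parameters
#'
#' Defaults emulate the study design (600 trials per picture category,
#' 256 sensors, 250 Hz, epochs -100..800 ms, three behavior systems) with
#' per-system effect amplitudes chosen so that fixed-window group
#' differences land near realistic values (EPN about -3 to -1 microvolts,
#' LPP about +3 to +1) and between-subject lognormal scaling gives paired
#' effect sizes around d = 2.
#'
#' @param nSubjects number of subjects.
#' @param nSensors sensors per montage.
#' @param fs sampling rate (Hz).
#' @param epochStart,epochEnd epoch limits in ms.
#' @param nTrialsPerCondition trials per condition per system.
#' @param systems behavior-system labels.
#' @param noiseSd per-sensor noise SD (microvolts).
#' @param noiseExponent spectral slope beta of 1/f^beta noise.
#' @param spatialCorr fraction of noise variance shared across sensors.
#' @param baseErpAmp condition-independent evoked peak (microvolts).
#' @param epnEffectAmp,lppEffectAmp per-system peak effect amplitudes
#'   (microvolts); recycled to \code{length(systems)}.
#' @param mirrorEffectAmp peak amplitude added on left-mirror trials.
#' @param effectLatency named (EPN, LPP) bump centers in ms.
#' @param effectSpan named (EPN, LPP) bump full widths in ms.
#' @param latencyJitterSd across-trial latency jitter SD (ms).
#' @param trialAmpSd across-trial additive amplitude SD (microvolts).
#' @param subjectScaleSdlog log-SD of per-subject lognormal effect scaling.
#' @param posteriorCluster,centralCluster sensor indices effects load on;
#'   defaults from \code{\link{defaultClusters}}.
#' @param seed root seed.
#' @return a \linkS4class{SyntheticParams}.
#' @export
syntheticParams <- function(nSubjects = 16L, nSensors = 256L, fs = 250,
                            epochStart = -100, epochEnd = 800,
                            nTrialsPerCondition = 600L,
                            systems = c("sexual_reproduction",
                                        "disease_avoidance",
                                        "predator_fear"),
                            noiseSd = 20, noiseExponent = 1,
                            spatialCorr = 0.3, baseErpAmp = 4,
                            epnEffectAmp = c(-3.3, -2.4, -1.5),
                            lppEffectAmp = c(3.0, 1.9, 0.9),
                            mirrorEffectAmp = 0,
                            effectLatency = c(EPN = 270, LPP = 430),
                            effectSpan = c(EPN = 120, LPP = 160),
                            latencyJitterSd = 10, trialAmpSd = 1,
                            subjectScaleSdlog = 0.45,
                            posteriorCluster = NULL, centralCluster = NULL,
                            seed = 20210806L) {
  cl <- defaultClusters(nSensors)
  if (is.null(posteriorCluster)) posteriorCluster <- cl$posterior
  if (is.null(centralCluster)) centralCluster <- cl$central
  epn <- rep_len(epnEffectAmp, length(systems))
  lpp <- rep_len(lppEffectAmp, length(systems))
  names(epn) <- names(lpp) <- systems
  new("SyntheticParams",
      nSubjects = as.integer(nSubjects), nSensors = as.integer(nSensors),
      fs = fs, epochStart = epochStart, epochEnd = epochEnd,
      nTrialsPerCondition = as.integer(nTrialsPerCondition),
      systems = systems, noiseSd = noiseSd, noiseExponent = noiseExponent,
      spatialCorr = spatialCorr, baseErpAmp = baseErpAmp,
      epnEffectAmp = epn, lppEffectAmp = lpp,
      mirrorEffectAmp = mirrorEffectAmp,
      effectLatency = effectLatency, effectSpan = effectSpan,
      latencyJitterSd = latencyJitterSd, trialAmpSd = trialAmpSd,
      subjectScaleSdlog = subjectScaleSdlog,
      posteriorCluster = as.integer(sort(posteriorCluster)),
      centralCluster = as.integer(sort(centralCluster)),
      seed = as.integer(seed))
}

# Check that each effect support fits its component search range; used by
# generateSubject so a misconfigured latency fails loudly with the name of
# the offending component.
checkEffectSupport <- function(params, searchRanges =
                                 list(EPN = c(150, 350), LPP = c(350, 750))) {
  for (comp in c("EPN", "LPP")) {
    lo <- params@effectLatency[[comp]] - params@effectSpan[[comp]] / 2
    hi <- params@effectLatency[[comp]] + params@effectSpan[[comp]] / 2
    if (lo < params@epochStart || hi > params@epochEnd)
      stop(sprintf("%s effect support [%g, %g] ms lies outside the epoch",
                   comp, lo, hi))
    rng <- searchRanges[[comp]]
    if (!is.null(rng) && (lo < rng[1L] - 1e-9 || hi > rng[2L] + 1e-9))
      stop(sprintf("%s effect support [%g, %g] ms lies outside its search range [%g, %g]",
                   comp, lo, hi, rng[1L], rng[2L]))
  }
  invisible(TRUE)
}

#' Generate one synthetic subject x system EpochSet
#'
#' Fully reproducible from \code{(params@seed, subjectIndex, system)}.
#'
#' @param params a \linkS4class{SyntheticParams}.
#' @param subjectIndex 1-based subject index (must be <= nSubjects).
#' @param system one of \code{params@systems}.
#' @param effectScale named numeric (EPN, LPP) multiplicative scale for this
#'   subject's effect amplitudes; \code{generateStudy} draws these from a
#'   lognormal distribution to emulate between-subject variation.
#' @return an \linkS4class{EpochSet} with \code{nTrialsPerCondition} trials
#'   per condition and balanced mirror labels within condition.
#' @export
generateSubject <- function(params, subjectIndex, system = params@systems[1L],
                            effectScale = c(EPN = 1, LPP = 1)) {
  validObject(params)
  if (params@fs <= 0) stop("sampling rate must be positive")
  if (subjectIndex < 1L || subjectIndex > params@nSubjects)
    stop("subjectIndex out of range")
  sysIdx <- match(system, params@systems)
  if (is.na(sysIdx)) stop("unknown system label: ", system)
  checkEffectSupport(params)

  step <- 1000 / params@fs
  time <- seq(params@epochStart, params@epochEnd, by = step)
  nS <- length(time)
  n <- params@nTrialsPerCondition
  nT <- 2L * n
  seed <- childSeed(params@seed, subjectIndex, sysIdx, 1L)

  withSeed(seed, {
    # design: permuted conditions, mirrors balanced within condition
    condition <- sample(rep(c("high", "low"), each = n))
    mirror <- character(nT)
    for (cond in c("high", "low")) {
      idx <- which(condition == cond)
      m <- rep(c("left", "right"), length.out = length(idx))
      mirror[idx] <- sample(m)
    }

    data <- array(0, dim = c(nT, params@nSensors, nS))

    # spatially correlated 1/f noise
    if (params@noiseSd > 0) {
      rho <- params@spatialCorr
      shared <- if (rho > 0)
        oneOverFNoise(nS, nT, params@noiseExponent) else NULL
      indep <- if (rho < 1)
        oneOverFNoise(nS, nT * params@nSensors, params@noiseExponent) else NULL
      for (s in seq_len(params@nSensors)) {
        tr <- matrix(0, nS, nT)
        if (!is.null(shared)) tr <- tr + sqrt(rho) * shared
        if (!is.null(indep))
          tr <- tr + sqrt(1 - rho) *
            indep[, ((s - 1L) * nT + 1L):(s * nT), drop = FALSE]
        data[, s, ] <- data[, s, ] + t(tr) * params@noiseSd
      }
    }

    # condition-independent evoked shape: positive-going on the posterior
    # cluster, negative-going on the central cluster (typical polarity of
    # posterior vs central ERPs), broad bump over 50-650 ms
    if (params@baseErpAmp != 0) {
      base <- params@baseErpAmp * hannTemplate(time, 350, 600)
      for (s in params@posteriorCluster)
        data[, s, ] <- sweep(data[, s, , drop = FALSE], 3L, base, "+")[, 1L, ]
      for (s in params@centralCluster)
        data[, s, ] <- sweep(data[, s, , drop = FALSE], 3L, -base, "+")[, 1L, ]
    }

    addBumps <- function(data, trialIdx, peakAmp, comp, cluster) {
      if (length(trialIdx) == 0L || peakAmp == 0) return(data)
      centers <- params@effectLatency[[comp]] +
        stats::rnorm(length(trialIdx), 0, params@latencyJitterSd)
      amps <- peakAmp + stats::rnorm(length(trialIdx), 0, params@trialAmpSd)
      span <- params@effectSpan[[comp]]
      W <- matrix(0, length(trialIdx), nS)
      for (k in seq_along(trialIdx))
        W[k, ] <- amps[k] * hannTemplate(time, centers[k], span)
      for (s in cluster)
        data[trialIdx, s, ] <- data[trialIdx, s, ] + W
      data
    }

    hi <- which(condition == "high")
    data <- addBumps(data, hi, effectScale[["EPN"]] *
                       params@epnEffectAmp[[system]], "EPN",
                     params@posteriorCluster)
    data <- addBumps(data, hi, effectScale[["LPP"]] *
                       params@lppEffectAmp[[system]], "LPP",
                     params@centralCluster)
    if (params@mirrorEffectAmp != 0) {
      left <- which(mirror == "left")
      data <- addBumps(data, left, params@mirrorEffectAmp, "EPN",
                       params@posteriorCluster)
    }

    epochSet(data, fs = params@fs, time = time,
             condition = condition, mirror = mirror,
             subjectId = sprintf("S%02d", subjectIndex), system = system,
             provenance = sprintf(
               "synthetic: seed=%d subject=%d system=%s scaleEPN=%.4f scaleLPP=%.4f",
               params@seed, subjectIndex, system,
               effectScale[["EPN"]], effectScale[["LPP"]]))
  })
}

#' Generate a full synthetic study
#'
#' One \linkS4class{EpochSet} per subject x system. Per-subject effect
#' amplitudes are scaled by lognormal factors (unit mean,
#' \code{subjectScaleSdlog} log-SD, drawn independently per subject x
#' system x component) to emulate between-subject variation in effect
#' magnitude.
#'
#' @param params a \linkS4class{SyntheticParams}.
#' @return named list of EpochSets, names \code{"<subject>.<system>"}.
#' @export
generateStudy <- function(params) {
  validObject(params)
  out <- list()
  for (i in seq_len(params@nSubjects)) {
    for (j in seq_along(params@systems)) {
      sys <- params@systems[j]
      scale <- withSeed(childSeed(params@seed, i, j, 2L), {
        if (params@subjectScaleSdlog > 0)
          stats::rlnorm(2, meanlog = -params@subjectScaleSdlog^2 / 2,
                        sdlog = params@subjectScaleSdlog)
        else c(1, 1)
      })
      names(scale) <- c("EPN", "LPP")
      es <- generateSubject(params, i, sys, effectScale = scale)
      out[[paste(sprintf("S%02d", i), sys, sep = ".")]] <- es
    }
  }
  out
}
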