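# Study orchestration and the calibration / power simulations.

#' Run a full synthetic study
#'
#' Generates all subject x system EpochSets, applies the preprocessing
#' chain (optional band limiting, baseline adjustment, average reference,
#' artifact rejection, trial equating), gates cases on the bootstrap SNR
#' criterion, runs the case analysis in both fixed and adaptive modes, the
#' specificity analysis, and the first/second-half habituation reanalysis,
#' and assembles the study-level tables.
#'
#' @param params a \linkS4class{SyntheticParams}.
#' @param specs component specifications; default derived from the
#'   montage size.
#' @param config a \linkS4class{BootstrapConfig}.
#' @param snr an \linkS4class{SnrConfig} used for the QC gate.
#' @param filter a \linkS4class{FilterSpec}, or \code{NULL} to skip band
#'   limiting (synthetic data are already band-limited by construction).
#' @param rejectThreshold artifact-rejection threshold (microvolts).
#' @param outDir optional directory; when given, all tables are written as
#'   CSV/JSON.
#' @return list with \code{caseResults}, \code{caseResultsFixed},
#'   \code{specificity}, \code{habituation}, \code{sensitivity},
#'   \code{falseAlarm}, \code{group}, \code{qc}.
#' @export
runStudy <- function(params, specs = NULL, config = bootstrapConfig(),
                     snr = snrConfig(nBoot = 1000L), filter = NULL,
                     rejectThreshold = 100, outDir = NULL) {
  if (is.null(specs))
    specs <- defaultComponentSpecs(params@nSensors,
                                   clusters = list(
                                     posterior = params@posteriorCluster,
                                     central = params@centralCluster))
  study <- generateStudy(params)
  qc <- qcReport(study, specs, snr)
  keep <- vapply(names(study), function(nm) {
    es <- study[[nm]]
    all(qc$pass[qc$subject == subjectId(es) &
                  qc$system == behaviorSystem(es)])
  }, logical(1L))
  study <- study[keep]
  if (length(study) == 0L) stop("QC gate excluded every case")

  prep <- lapply(study, function(es) {
    if (!is.null(filter)) es <- applyFilters(es, filter)
    es <- baselineAndReference(es)
    es <- rejectArtifacts(es, rejectThreshold)$epochs
    equateTrials(es, seed = childSeed(params@seed, 77L,
                                      match(subjectId(es),
                                            sprintf("S%02d",
                                                    seq_len(params@nSubjects)))))
  })

  caseA <- do.call(rbind, lapply(prep, runCaseAnalysis, specs = specs,
                                 config = config, mode = "adaptive"))
  caseF <- do.call(rbind, lapply(prep, runCaseAnalysis, specs = specs,
                                 config = config, mode = "fixed"))
  spc <- do.call(rbind, lapply(prep, runSpecificity, specs = specs,
                               config = config, mode = "adaptive"))
  hab <- do.call(rbind, lapply(prep, function(es) {
    hv <- splitHalves(es)
    rbind(cbind(half = "first",
                runCaseAnalysis(hv$first, specs, config, "adaptive")),
          cbind(half = "second",
                runCaseAnalysis(hv$second, specs, config, "adaptive")))
  }))
  rownames(caseA) <- rownames(caseF) <- rownames(spc) <- rownames(hab) <- NULL

  scores <- caseF[, c("subject", "system", "component",
                      "observed_difference")]
  names(scores)[4L] <- "difference"
  out <- list(caseResults = caseA, caseResultsFixed = caseF,
              specificity = spc, habituation = hab,
              sensitivity = sensitivityTable(caseA, config@criteria),
              falseAlarm = falseAlarmTable(spc, config@criteria),
              group = groupStats(scores), qc = qc)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(caseA, file.path(outDir, "case_results.csv"),
                     row.names = FALSE)
    utils::write.csv(caseF, file.path(outDir, "case_results_fixed.csv"),
                     row.names = FALSE)
    utils::write.csv(spc, file.path(outDir, "specificity.csv"),
                     row.names = FALSE)
    utils::write.csv(out$sensitivity,
                     file.path(outDir, "sensitivity_table.csv"),
                     row.names = FALSE)
    utils::write.csv(out$falseAlarm,
                     file.path(outDir, "false_alarm_table.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(outDir, "qc.csv"), row.names = FALSE)
    jsonlite::write_json(out$group, file.path(outDir, "group_stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

# Small null-study parameter set shared by the calibration simulations:
# no injected effects, desk-scale montage and trial counts.
nullParams <- function(nTrials, nSensors = 16L, seed = 1L) {
  syntheticParams(nSubjects = 1L, nSensors = nSensors,
                  nTrialsPerCondition = as.integer(nTrials),
                  systems = "null_system", noiseSd = 20,
                  epnEffectAmp = 0, lppEffectAmp = 0, baseErpAmp = 0,
                  trialAmpSd = 0, latencyJitterSd = 0,
                  subjectScaleSdlog = 0, seed = seed)
}

#' Null-calibration simulation of the single-subject test
#'
#' Generates effect-free synthetic subjects and runs the one-sided
#' bootstrap test for both components in the requested window mode,
#' returning the rejection rate at each criterion. With fixed windows the
#' test is calibrated (rate approximately alpha); with adaptive windows
#' under the fixed_observed policy the rate exceeds alpha, the mechanism
#' behind elevated mirror-split false-alarm rates.
#'
#' @param nSubjects simulated null subjects.
#' @param nTrials trials per condition per subject.
#' @param nBoot bootstrap replicates per test.
#' @param mode \code{"fixed"}, \code{"adaptive"}, or \code{"both"} (the
#'   two modes share each subject's generated data).
#' @param seed integer seed.
#' @param nSensors montage size.
#' @param alpha criterion at which the rejection rate is reported.
#' @return for a single mode, a list with \code{rate}, \code{nTests},
#'   \code{rejections} and the per-test p-values \code{p}; for
#'   \code{"both"}, a list with elements \code{fixed} and \code{adaptive}
#'   of that form.
#' @export
simulateNullRejection <- function(nSubjects = 500L, nTrials = 100L,
                                  nBoot = 2000L,
                                  mode = c("fixed", "adaptive", "both"),
                                  seed = 1L, nSensors = 16L, alpha = 0.05) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("fixed", "adaptive") else mode
  specs <- defaultComponentSpecs(nSensors)
  cfg <- bootstrapConfig(nBoot = nBoot, seed = seed)
  p <- stats::setNames(rep(list(numeric(0)), length(modes)), modes)
  for (i in seq_len(nSubjects)) {
    par <- nullParams(nTrials, nSensors,
                      seed = childSeed(seed, 1000L + i))
    es <- generateSubject(par, 1L, "null_system")
    es <- baselineAndReference(es)
    cfg@seed <- childSeed(seed, 2000L + i)
    for (m in modes) {
      res <- runCaseAnalysis(es, specs, cfg, m)
      p[[m]] <- c(p[[m]], res$p_one_sided)
    }
  }
  summarise <- function(pv) {
    rej <- sum(pv < alpha)
    list(rate = rej / length(pv), nTests = length(pv), rejections = rej,
         p = pv)
  }
  if (mode == "both") lapply(p, summarise) else summarise(p[[mode]])
}

#' Power and adaptive-window recovery simulation
#'
#' Injects an EPN effect whose fixed-window mean difference equals
#' \code{effectSe} times the standard error of that window-mean difference
#' (estimated analytically from pilot per-trial score SDs of the same
#' generator), then measures the proportion of subjects significant at
#' \code{alpha} and the proportion whose adaptive window overlaps the
#' injected effect support.
#'
#' @param nSubjectsSim simulated subjects.
#' @param nTrials trials per condition.
#' @param effectSe injected effect size in units of the SE of the
#'   window-mean difference (default 4).
#' @param nBoot bootstrap replicates per test.
#' @param seed integer seed.
#' @param nSensors montage size.
#' @param alpha significance criterion.
#' @return list with \code{power}, \code{windowOverlap}, \code{se},
#'   \code{peakAmp}, \code{n}.
#' @export
simulatePowerRecovery <- function(nSubjectsSim = 100L, nTrials = 600L,
                                  effectSe = 4, nBoot = 2000L, seed = 1L,
                                  nSensors = 16L, alpha = 0.05) {
  specs <- defaultComponentSpecs(nSensors)
  epn <- specs$EPN
  # pilot: per-trial score SD of the null generator in the fixed window
  pilot <- nullParams(200L, nSensors, seed = childSeed(seed, 3L))
  esP <- baselineAndReference(generateSubject(pilot, 1L, "null_system"))
  sdScore <- stats::sd(perTrialScores(esP, epn@cluster, epn@fixedWindow))
  se <- sdScore * sqrt(2 / nTrials)
  # peak template amplitude whose fixed-window mean difference after
  # preprocessing is effectSe * se: divide by the mean Hanning weight over
  # that window, and by the average-reference attenuation (subtracting the
  # across-sensor mean scales a k-of-n cluster-confined effect by 1 - k/n)
  time <- timeAxis(esP)
  idx <- windowSamples(time, epn@fixedWindow, closed = "both")
  span <- 120; latency <- 270
  wbar <- mean(hannTemplate(time, latency, span)[idx])
  atten <- 1 - length(epn@cluster) / nSensors
  peak <- -effectSe * se / (wbar * atten)
  support <- c(latency - span / 2, latency + span / 2)

  sig <- logical(nSubjectsSim)
  overlap <- logical(nSubjectsSim)
  for (i in seq_len(nSubjectsSim)) {
    par <- syntheticParams(nSubjects = 1L, nSensors = nSensors,
                           nTrialsPerCondition = as.integer(nTrials),
                           systems = "sim", noiseSd = 20,
                           epnEffectAmp = peak, lppEffectAmp = 0,
                           baseErpAmp = 0, trialAmpSd = 0,
                           latencyJitterSd = 0, subjectScaleSdlog = 0,
                           effectLatency = c(EPN = latency, LPP = 430),
                           effectSpan = c(EPN = span, LPP = 160),
                           seed = childSeed(seed, 4000L + i))
    es <- baselineAndReference(generateSubject(par, 1L, "sim"))
    cfg <- bootstrapConfig(nBoot = nBoot, seed = childSeed(seed, 5000L + i))
    res <- runCaseAnalysis(es, list(EPN = epn), cfg, "adaptive")
    sig[i] <- res$p_one_sided < alpha
    overlap[i] <- res$window_end >= support[1L] &&
      res$window_start <= support[2L]
  }
  list(power = mean(sig), windowOverlap = mean(overlap), se = se,
       peakAmp = peak, n = nSubjectsSim)
}

#' SNR confidence-interval coverage simulation
#'
#' Builds subjects with a known post/pre RMS ratio (a fixed post-stimulus
#' evoked shape plus white per-sample noise) and measures how often the
#' bootstrap percentile CI covers the true dB value.
#'
#' @param nSim simulated subjects.
#' @param nTrialsSim trials per subject.
#' @param sigma per-sample noise SD (microvolts).
#' @param signalRms RMS amplitude of the evoked shape over the
#'   post-stimulus window (microvolts).
#' @param nBoot bootstrap replicates per CI.
#' @param seed integer seed.
#' @return list with \code{coverage}, \code{trueDb}, \code{n}.
#' @export
simulateSnrCoverage <- function(nSim = 100L, nTrialsSim = 60L, sigma = 1,
                                signalRms = 0.6, nBoot = 1000L, seed = 1L) {
  fs <- 250
  time <- seq(-100, 800, by = 1000 / fs)
  post <- time > 0
  sig <- numeric(length(time))
  shape <- hannTemplate(time, 400, 700) * (time > 0)
  sig[post] <- shape[post] * signalRms / sqrt(mean(shape[post]^2))
  # each replicate averages nMin = the smaller condition count; the
  # estimand is the SNR of that nMin-trial average:
  # (signal RMS^2 + sigma^2/nMin) vs sigma^2/nMin
  nMin <- nTrialsSim %/% 2L
  trueDb <- 10 * log10((signalRms^2 + sigma^2 / nMin) / (sigma^2 / nMin))
  cover <- logical(nSim)
  for (i in seq_len(nSim)) {
    noise <- withSeed(childSeed(seed, 6000L + i),
                      array(stats::rnorm(nTrialsSim * length(time), 0,
                                         sigma),
                            dim = c(nTrialsSim, 1L, length(time))))
    data <- sweep(noise, 3L, sig, "+")
    es <- epochSet(data, fs = fs, time = time,
                   condition = rep_len(c("high", "low"), nTrialsSim))
    r <- snrCi(es, 1L, snrConfig(nBoot = nBoot,
                                 seed = childSeed(seed, 7000L + i)))
    cover[i] <- r$lowerDb <= trueDb && trueDb <= r$upperDb
  }
  list(coverage = mean(cover), trueDb = trueDb, n = nSim)
}
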