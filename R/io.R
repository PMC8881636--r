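# Plain-text epoch container and config I/O.
#
# An EpochSet is stored as a directory holding:
#   header.json  - fs, time axis, dims, subject, system, provenance
#   data.tsv     - (trials*sensors) x samples amplitude matrix, trial-major
#   metadata.csv - columns exactly: trial_index, condition, mirror
# Everything is text so containers survive plain-file round trips.

#' Write an EpochSet to a directory
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeEpochSet <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs@data)
  header <- list(fs = samplingRate(epochs), time = timeAxis(epochs),
                 n_trials = d[1L], n_sensors = d[2L], n_samples = d[3L],
                 subject_id = subjectId(epochs),
                 system = behaviorSystem(epochs),
                 provenance = epochs@provenance)
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  m <- matrix(aperm(epochs@data, c(3L, 2L, 1L)), ncol = d[3L], byrow = TRUE)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- data.frame(trial_index = seq_len(d[1L]),
                     condition = conditionLabels(epochs),
                     mirror = mirrorLabels(epochs))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an EpochSet written by \code{\link{writeEpochSet}}
#'
#' @param dir the container directory.
#' @return an \linkS4class{EpochSet}.
#' @export
readEpochSet <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(file.path(dir, "data.tsv"), sep = "\t"))
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  d <- c(header$n_trials, header$n_sensors, header$n_samples)
  data <- aperm(array(t(m), dim = c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
  epochSet(data, fs = header$fs, time = header$time,
           condition = meta$condition, mirror = meta$mirror,
           subjectId = header$subject_id, system = header$system,
           provenance = header$provenance)
}

#' Write an artifact-rejection log as JSON lines
#'
#' One JSON object per rejected trial with fields trial_index, sensor,
#' sample, value.
#'
#' @param log data.frame from \code{\link{rejectArtifacts}}.
#' @param path output file.
#' @export
writeRejectionLog <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i)
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write SyntheticParams as YAML
#'
#' @param params a \linkS4class{SyntheticParams}.
#' @param path YAML file path.
#' @return \code{syntheticParamsToYaml} returns \code{path} invisibly;
#'   \code{syntheticParamsFromYaml} returns a
#'   \linkS4class{SyntheticParams}.
#' @export
syntheticParamsToYaml <- function(params, path) {
  fields <- list(
    nSubjects = params@nSubjects, nSensors = params@nSensors,
    fs = params@fs, epochStart = params@epochStart,
    epochEnd = params@epochEnd,
    nTrialsPerCondition = params@nTrialsPerCondition,
    systems = as.list(params@systems), noiseSd = params@noiseSd,
    noiseExponent = params@noiseExponent, spatialCorr = params@spatialCorr,
    baseErpAmp = params@baseErpAmp,
    epnEffectAmp = as.list(params@epnEffectAmp),
    lppEffectAmp = as.list(params@lppEffectAmp),
    mirrorEffectAmp = params@mirrorEffectAmp,
    effectLatency = as.list(params@effectLatency),
    effectSpan = as.list(params@effectSpan),
    latencyJitterSd = params@latencyJitterSd,
    trialAmpSd = params@trialAmpSd,
    subjectScaleSdlog = params@subjectScaleSdlog,
    posteriorCluster = params@posteriorCluster,
    centralCluster = params@centralCluster, seed = params@seed)
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname syntheticParamsToYaml
#' @export
syntheticParamsFromYaml <- function(path) {
  f <- yaml::read_yaml(path)
  syntheticParams(
    nSubjects = f$nSubjects, nSensors = f$nSensors, fs = f$fs,
    epochStart = f$epochStart, epochEnd = f$epochEnd,
    nTrialsPerCondition = f$nTrialsPerCondition,
    systems = unlist(f$systems), noiseSd = f$noiseSd,
    noiseExponent = f$noiseExponent, spatialCorr = f$spatialCorr,
    baseErpAmp = f$baseErpAmp, epnEffectAmp = unlist(f$epnEffectAmp),
    lppEffectAmp = unlist(f$lppEffectAmp),
    mirrorEffectAmp = f$mirrorEffectAmp,
    effectLatency = unlist(f$effectLatency),
    effectSpan = unlist(f$effectSpan),
    latencyJitterSd = f$latencyJitterSd, trialAmpSd = f$trialAmpSd,
    subjectScaleSdlog = f$subjectScaleSdlog,
    posteriorCluster = f$posteriorCluster,
    centralCluster = f$centralCluster, seed = f$seed)
}

#' Load a sensor-cluster definition from JSON
#'
#' Cluster files are JSON objects \code{{"name": ..., "sensor_ids": [...]}};
#' the published 256-net EPN/LPP clusters ship with the package under
#' \code{extdata/}.
#'
#' @param path JSON file path.
#' @return list with \code{name} and integer \code{sensor_ids}.
#' @export
readClusterJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(name = x$name, sensor_ids = as.integer(x$sensor_ids))
}
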