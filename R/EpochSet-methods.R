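#' Construct an EpochSet
#'
#' @param data trials x sensors x samples numeric array (microvolts).
#' @param fs sampling rate in Hz.
#' @param time sample times in ms; if \code{NULL}, derived from \code{fs}
#'   assuming the epoch contains time 0 at sample \code{tZeroIndex}.
#' @param condition per-trial condition labels (\code{"high"}/\code{"low"}).
#' @param mirror per-trial mirror labels (\code{"left"}/\code{"right"});
#'   defaults to \code{"left"} for all trials.
#' @param subjectId,system,provenance identification strings.
#' @param tZeroIndex 1-based index of the sample at 0 ms when \code{time}
#'   is derived.
#' @return an \linkS4class{EpochSet}.
#' @examples
#' es <- epochSet(array(0, c(4, 2, 10)), fs = 100,
#'                condition = rep(c("high", "low"), 2))
#' nTrials(es)
#' @export
epochSet <- function(data, fs, time = NULL, condition,
                     mirror = rep("left", dim(data)[1L]),
                     subjectId = "S01", system = "unspecified",
                     provenance = "constructed", tZeroIndex = 1L) {
  if (is.null(time))
    time <- (seq_len(dim(data)[3L]) - tZeroIndex) * 1000 / fs
  if (length(condition) != dim(data)[1L])
    stop("condition labels must have length = number of trials")
  if (length(mirror) != dim(data)[1L])
    stop("mirror labels must have length = number of trials")
  new("EpochSet", data = data, fs = fs, time = time,
      trialData = DataFrame(condition = as.character(condition),
                            mirror = as.character(mirror)),
      subjectId = subjectId, system = system, provenance = provenance)
}

#' Accessors for EpochSet
#'
#' @param x an \linkS4class{EpochSet}.
#' @name EpochSet-accessors
#' @aliases epochData samplingRate timeAxis trialInfo conditionLabels
#'   mirrorLabels nTrials nSensors subjectId behaviorSystem
NULL

#' @rdname EpochSet-accessors
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname EpochSet-accessors
#' @export
setMethod("timeAxis", "EpochSet", function(x) x@time)

#' @rdname EpochSet-accessors
#' @export
setMethod("trialInfo", "EpochSet", function(x) x@trialData)

#' @rdname EpochSet-accessors
#' @export
setMethod("conditionLabels", "EpochSet", function(x) x@trialData$condition)

#' @rdname EpochSet-accessors
#' @export
setMethod("mirrorLabels", "EpochSet", function(x) x@trialData$mirror)

#' @rdname EpochSet-accessors
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])

#' @rdname EpochSet-accessors
#' @export
setMethod("nSensors", "EpochSet", function(x) dim(x@data)[2L])

#' @rdname EpochSet-accessors
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)

#' @rdname EpochSet-accessors
#' @export
setMethod("behaviorSystem", "EpochSet", function(x) x@system)

#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "ERPWaveform", function(x) x@fs)

#' @rdname EpochSet-accessors
#' @export
setMethod("timeAxis", "ERPWaveform", function(x) x@time)

#' Subset trials of an EpochSet
#'
#' @param x an \linkS4class{EpochSet}.
#' @param i trial indices or logical mask.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochSet",
      data = x@data[i, , , drop = FALSE], fs = x@fs, time = x@time,
      trialData = x@trialData[i, , drop = FALSE],
      subjectId = x@subjectId, system = x@system, provenance = x@provenance)
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  tab <- table(object@trialData$condition)
  cat(sprintf(
    "EpochSet: subject %s, system %s\n  %d trials x %d sensors x %d samples (%g Hz, %g..%g ms)\n  conditions: %s\n",
    object@subjectId, object@system, d[1L], d[2L], d[3L], object@fs,
    min(object@time), max(object@time),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ERPWaveform", function(object) {
  cat(sprintf("ERPWaveform (%s): %d sensors x %d samples, %d trials averaged\n",
              object@condition, nrow(object@data), ncol(object@data),
              object@nTrials))
})

setMethod("show", "ComponentSpec", function(object) {
  cat(sprintf(
    "ComponentSpec %s: cluster %s (%d sensors), fixed %g-%g ms, search %g-%g ms, span %g ms, direction %+d\n",
    object@name, object@clusterName, length(object@cluster),
    object@fixedWindow[1L], object@fixedWindow[2L],
    object@searchRange[1L], object@searchRange[2L],
    object@span, object@direction))
})
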