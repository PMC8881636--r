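#' @rdname EpochSet-accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("mirrorLabels", function(x) standardGeneric("mirrorLabels"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("behaviorSystem", function(x) standardGeneric("behaviorSystem"))
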