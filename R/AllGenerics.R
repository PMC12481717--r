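#' Accessors for pipeline containers
#'
#' @param object an \linkS4class{EEGRecording}, \linkS4class{EpochSet},
#'   \linkS4class{Evoked} or \linkS4class{CVSeries}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("timeMs", function(object) standardGeneric("timeMs"))
#' @rdname accessors
#' @export
setGeneric("keptMask", function(object) standardGeneric("keptMask"))
#' @rdname accessors
#' @export
setGeneric("trialLevels", function(object) standardGeneric("trialLevels"))
#' @rdname accessors
#' @export
setGeneric("subjectMeta", function(object) standardGeneric("subjectMeta"))
#' @rdname accessors
#' @export
setGeneric("processingLog", function(object) standardGeneric("processingLog"))

#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelNames", "Evoked", function(object) object@channelNames)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(object) object@rate)
#' @rdname accessors
setMethod("eventTable", "EEGRecording", function(object) object@events)
#' @rdname accessors
setMethod("signalData", "EEGRecording", function(object) object@data)
#' @rdname accessors
setMethod("signalData", "EpochSet", function(object) object@data)
#' @rdname accessors
setMethod("signalData", "Evoked", function(object) object@data)
#' @rdname accessors
setMethod("timeMs", "EpochSet", function(object) object@timeMs)
#' @rdname accessors
setMethod("timeMs", "Evoked", function(object) object@timeMs)
#' @rdname accessors
setMethod("keptMask", "EpochSet", function(object) object@keptMask)
#' @rdname accessors
setMethod("trialLevels", "EpochSet", function(object) object@levels)
#' @rdname accessors
setMethod("subjectMeta", "EEGRecording", function(object) object@subjectMeta)
#' @rdname accessors
setMethod("subjectMeta", "EpochSet", function(object) object@subjectMeta)
#' @rdname accessors
setMethod("subjectMeta", "Evoked", function(object) object@subjectMeta)
#' @rdname accessors
setMethod("processingLog", "EpochSet", function(object) object@log)
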