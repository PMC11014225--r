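NULL

#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @export
setGeneric("rtime", function(object) standardGeneric("rtime"))

#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @export
setGeneric("processingStage", function(object) standardGeneric("processingStage"))

#' @export
setGeneric("libraryRecords", function(object) standardGeneric("libraryRecords"))

#' @export
setGeneric("rtTolerance", function(object) standardGeneric("rtTolerance"))

#' @export
setGeneric("featureRT", function(object) standardGeneric("featureRT"))

#' @export
setGeneric("featureAnnotation", function(object) standardGeneric("featureAnnotation"))

#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @export
setGeneric("transformDescriptor", function(object) standardGeneric("transformDescriptor"))

#' @export
setGeneric("trainSamples", function(object) standardGeneric("trainSamples"))

#' @export
setGeneric("bestSubset", function(object) standardGeneric("bestSubset"))

#' @export
setGeneric("subsetRanking", function(object) standardGeneric("subsetRanking"))

#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))
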