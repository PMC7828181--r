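# Accessor generics.  Slot access stays internal; user code goes through
# these.

#' @rdname accessors
#' @export
setGeneric("blockSize", function(x) standardGeneric("blockSize"))
#' @rdname accessors
#' @export
setGeneric("searchWindow", function(x) standardGeneric("searchWindow"))
#' @rdname accessors
#' @export
setGeneric("looks", function(x) standardGeneric("looks"))
#' @rdname accessors
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))
#' @rdname accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setGeneric("vesselness", function(x) standardGeneric("vesselness"))
#' @rdname accessors
#' @export
setGeneric("fovMask", function(x) standardGeneric("fovMask"))
#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))
#' @rdname accessors
#' @export
setGeneric("runLog", function(x) standardGeneric("runLog"))

#' Accessors
#'
#' Read-only accessors for the parameter and result classes:
#' \code{blockSize}, \code{searchWindow} and \code{looks} on
#' \code{\link{DenoiserParams}}; \code{ensembleMembers} on
#' \code{\link{EnsembleConfig}}; \code{vesselMask}, \code{vesselness},
#' \code{fovMask}, \code{thresholdValue} and \code{runLog} on
#' \code{\linkS4class{SegmentationResult}}.
#'
#' @param x the object.
#' @return the corresponding field.
#' @name accessors
#' @aliases blockSize searchWindow looks ensembleMembers vesselMask
#'   vesselness fovMask thresholdValue runLog
NULL

setMethod("blockSize", "DenoiserParams", function(x) x@blockSize)
setMethod("searchWindow", "DenoiserParams", function(x) x@searchWindow)
setMethod("looks", "DenoiserParams", function(x) x@looks)
setMethod("ensembleMembers", "EnsembleConfig", function(x) x@members)
setMethod("ensembleMembers", "PipelineConfig", function(x) x@ensemble@members)
setMethod("vesselMask", "SegmentationResult", function(x) x@mask)
setMethod("vesselness", "SegmentationResult", function(x) x@vesselness)
setMethod("fovMask", "SegmentationResult", function(x) x@fov)
setMethod("thresholdValue", "SegmentationResult", function(x) x@threshold)
setMethod("runLog", "SegmentationResult", function(x) x@log)
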