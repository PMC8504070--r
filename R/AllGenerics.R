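#' @rdname experimentalMatrix
#' @export
setGeneric("experimentalMatrix", function(x) standardGeneric("experimentalMatrix"))

#' @rdname experimentalMatrix
#' @export
setGeneric("backgroundMatrix", function(x) standardGeneric("backgroundMatrix"))

#' @rdname experimentalMatrix
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))

#' @rdname experimentalMatrix
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname ClipperResult-accessors
#' @export
setGeneric("contrastScores", function(x) standardGeneric("contrastScores"))

#' @rdname ClipperResult-accessors
#' @export
setGeneric("scoreCutoff", function(x) standardGeneric("scoreCutoff"))

#' @rdname ClipperResult-accessors
#' @export
setGeneric("discoveries", function(x) standardGeneric("discoveries"))

#' @rdname ClipperResult-accessors
#' @export
setGeneric("discoveryIndices", function(x) standardGeneric("discoveryIndices"))

#' @rdname ClipperResult-accessors
#' @export
setGeneric("fdrEstimates", function(x) standardGeneric("fdrEstimates"))

#' @rdname resultTable
#' @export
setGeneric("resultTable", function(x, ...) standardGeneric("resultTable"))
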