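#' @rdname x1Matrix
#' @export
setGeneric("x1Matrix", function(x) standardGeneric("x1Matrix"))

#' @rdname x1Matrix
#' @export
setGeneric("x2Matrix", function(x) standardGeneric("x2Matrix"))

#' @rdname x1Matrix
#' @export
setGeneric("incidentMatrix", function(x) standardGeneric("incidentMatrix"))

#' @rdname x1Matrix
#' @export
setGeneric("eventCodes", function(x) standardGeneric("eventCodes"))

#' @rdname x1Matrix
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname x1Matrix
#' @export
setGeneric("observedBoth", function(x) standardGeneric("observedBoth"))

#' @rdname graphNodes
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graphNodes
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname graphNodes
#' @export
setGeneric("graphScoreOf", function(x) standardGeneric("graphScoreOf"))

#' @rdname graphNodes
#' @export
setGeneric("graphSteps", function(x) standardGeneric("graphSteps"))

#' @rdname graphNodes
#' @export
setGeneric("nodeModels", function(x) standardGeneric("nodeModels"))

#' @rdname precedencePairs
#' @export
setGeneric("precedencePairs", function(x) standardGeneric("precedencePairs"))

#' @rdname stabilityTable
#' @export
setGeneric("stabilityTable", function(x) standardGeneric("stabilityTable"))

#' @rdname stabilityTable
#' @export
setGeneric("ambiguousPct", function(x) standardGeneric("ambiguousPct"))

#' @rdname trueEdges
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))
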