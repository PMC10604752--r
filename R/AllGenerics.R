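#' @rdname PrincipalTree-class
#' @param x a `PrincipalTree` or `RootedTree`.
#' @export
setGeneric("nodePositions", function(x) standardGeneric("nodePositions"))

#' @rdname PrincipalTree-class
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @rdname PrincipalTree-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname RootedTree-class
#' @export
setGeneric("treeLeaves", function(x) standardGeneric("treeLeaves"))

#' @rdname RootedTree-class
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname CumulativeStates-class
#' @param x a `CumulativeStates`.
#' @export
setGeneric("statePids", function(x) standardGeneric("statePids"))

#' @rdname CumulativeStates-class
#' @export
setGeneric("stateDates", function(x) standardGeneric("stateDates"))

#' @rdname CumulativeStates-class
#' @export
setGeneric("isPreState", function(x) standardGeneric("isPreState"))

#' @rdname CumulativeStates-class
#' @export
setGeneric("diseaseCodes", function(x) standardGeneric("diseaseCodes"))

#' @rdname SyntheticCohort-class
#' @param x a `SyntheticCohort`.
#' @export
setGeneric("caseRecords", function(x) standardGeneric("caseRecords"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("controlRecords", function(x) standardGeneric("controlRecords"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("controlMatching", function(x) standardGeneric("controlMatching"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("demographics", function(x) standardGeneric("demographics"))

#' @rdname StateEmbedding-class
#' @param x a `StateEmbedding`.
#' @export
setGeneric("stateScores", function(x) standardGeneric("stateScores"))

#' @rdname StateEmbedding-class
#' @export
setGeneric("stateWeights", function(x) standardGeneric("stateWeights"))

#' @rdname StateEmbedding-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
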